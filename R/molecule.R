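#' Parse a structure into a molecule record
#'
#' Parses a SMILES string or an SDF (V2000) block into a `MoleculeRecord`,
#' the unit of analysis used throughout the package. Multi-fragment inputs
#' (salts, mixtures) are reduced to their largest organic fragment, mirroring
#' the major-component convention used when curating macrocyclic drug sets
#' (e.g. keeping only the dominant congener of an antibiotic mixture).
#'
#' @param text A SMILES string, or a complete SDF/MOL V2000 block.
#' @param id Identifier for the record.
#' @param name Human-readable name; defaults to `id`.
#' @param route Administration route label: `"oral"`, `"parenteral"` or
#'   `"unknown"`.
#' @param origin Compound origin: `"original_natural_product"`,
#'   `"natural_product_derivative"`, `"de_novo"` or `NA`.
#' @return A `MoleculeRecord`: a list with the parsed neutral structure
#'   (`sdf_neutral`, canonical `smiles_neutral`), macrocycle annotation
#'   (`largest_ring_size`, `is_macrocycle`), flags (`contains_metal`,
#'   `mixture_major_component`) and the study labels. The pH-7 fields
#'   (`smiles_ph7`, `mol_ph7`) are filled by [protonate_ph7()].
#' @seealso [detect_macrocycle()], [protonate_ph7()], [compute_panel()]
#' @examples
#' rec <- parse_structure("C1CCCCCCCCCCC1", id = "cyclododecane")
#' rec$is_macrocycle
#' @export
parse_structure <- function(text, id, name = id,
                            route = c("unknown", "oral", "parenteral"),
                            origin = NA_character_) {
  route <- match.arg(route)
  if (!is.na(origin)) {
    origin <- match.arg(origin, c("original_natural_product",
                                  "natural_product_derivative", "de_novo"))
  }
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  is_sdf <- grepl("V2000", text, fixed = TRUE)
  sdfset <- if (is_sdf) .read_sdf_block(text, id) else .read_smiles(text, id)
  sdf <- sdfset[[1]]
  if (nrow(ChemmineR::atomblock(sdf)) == 0) {
    stop("parse error for '", id, "': empty molecule", call. = FALSE)
  }
  frag <- .largest_organic_fragment(sdf)
  sdf <- frag$sdf
  mol <- .build_mol(sdf)
  smiles_neutral <- .to_smiles(sdf, id)
  lrs <- if (length(mol$rings)) max(lengths(mol$rings)) else 0L
  rec <- structure(list(
    id = id, name = name,
    smiles_input = if (is_sdf) NA_character_ else text,
    smiles_neutral = smiles_neutral,
    smiles_ph7 = NA_character_,
    sdf_neutral = sdf, sdf_ph7 = NULL,
    mol_neutral = mol, mol_ph7 = NULL,
    largest_ring_size = as.integer(lrs),
    is_macrocycle = lrs >= 12L,
    origin = origin, route = route,
    contains_metal = !all(mol$elements %in% .ORGANIC_ELEMENTS),
    mixture_major_component = frag$multi
  ), class = "MoleculeRecord")
  rec
}

#' @export
print.MoleculeRecord <- function(x, ...) {
  cat("<MoleculeRecord>", x$id, if (!identical(x$name, x$id)) x$name, "\n")
  cat("  neutral SMILES:", x$smiles_neutral, "\n")
  if (!is.na(x$smiles_ph7)) cat("  pH 7.0 SMILES: ", x$smiles_ph7, "\n")
  cat("  largest ring:", x$largest_ring_size,
      if (x$is_macrocycle) "(macrocycle)" else "(not a macrocycle)", "\n")
  if (x$contains_metal) cat("  contains metal: descriptors unavailable\n")
  if (x$mixture_major_component) cat("  major component of a mixture\n")
  invisible(x)
}

.read_smiles <- function(smiles, id) {
  sm <- stats::setNames(smiles, id)
  tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(sm)),
    error = function(e) {
      stop("parse error for '", id, "': invalid SMILES '", smiles, "'",
           call. = FALSE)
    })
}

.read_sdf_block <- function(text, id) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^\\${4}", lines))) lines <- c(lines, "$$$$")
  writeLines(lines, tf)
  out <- tryCatch(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(tf)),
                  error = function(e) {
                    stop("parse error for '", id, "': invalid SDF block",
                         call. = FALSE)
                  })
  out
}

.to_smiles <- function(sdf, id) {
  ss <- methods::new("SDFset", SDF = list(sdf), ID = id)
  unname(as.character(ChemmineR::sdf2smiles(ss))[1])
}

# Split a (possibly multi-fragment) SDF into connected components and keep
# the largest organic fragment. Ties are broken by molecular weight, then by
# canonical SMILES order, making mixture handling deterministic.
.largest_organic_fragment <- function(sdf) {
  mol <- .build_mol(sdf)
  n <- length(mol$elements)
  comp <- integer(n)
  ncomp <- 0L
  adj <- lapply(seq_len(n), function(i) .neighbors(mol, i))
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0) { comp[w] <- ncomp; queue <- c(queue, w) }
    }
  }
  if (ncomp == 1L) return(list(sdf = sdf, multi = FALSE))
  frags <- lapply(seq_len(ncomp), function(k) which(comp == k))
  has_c <- vapply(frags, function(ix) any(mol$elements[ix] == "C"), logical(1))
  if (any(has_c)) frags <- frags[has_c]
  heavy_n <- vapply(frags, function(ix) sum(mol$heavy[ix]), integer(1))
  mw <- vapply(frags, function(ix) {
    w <- .ATOMIC_WEIGHTS[mol$elements[ix]]
    sum(w, na.rm = TRUE) + sum(mol$nH[ix][mol$heavy[ix]]) * 1.008
  }, numeric(1))
  smi <- vapply(seq_along(frags), function(k) {
    .to_smiles(.subset_sdf(sdf, frags[[k]]), paste0("frag", k))
  }, character(1))
  ord <- order(-heavy_n, -mw, smi)
  list(sdf = .subset_sdf(sdf, frags[[ord[1]]]), multi = TRUE)
}

# Subset an SDF object to the given atom indices, renumbering atoms/bonds
# and fixing the V2000 counts line.
.subset_sdf <- function(sdf, idx) {
  ab <- ChemmineR::atomblock(sdf)
  bt <- .bond_table(sdf)
  keep_b <- bt$a1 %in% idx & bt$a2 %in% idx
  ab2 <- ab[idx, , drop = FALSE]
  el <- sub("_\\d+$", "", rownames(ab)[idx])
  rownames(ab2) <- paste(el, seq_along(idx), sep = "_")
  bb2 <- cbind(C1 = match(bt$a1[keep_b], idx),
               C2 = match(bt$a2[keep_b], idx),
               C3 = bt$order[keep_b])
  if (nrow(bb2)) rownames(bb2) <- as.character(seq_len(nrow(bb2)))
  hdr <- sdf@header
  cl <- grep("Counts", names(hdr))
  if (!length(cl)) cl <- 4L
  hdr[cl] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(ab2), nrow(bb2))
  new_sdf <- sdf
  new_sdf@header <- hdr
  new_sdf@atomblock <- ab2
  new_sdf@bondblock <- bb2
  new_sdf
}

#' Detect the macrocyclic ring of a molecule
#'
#' Reports the largest ring in the smallest set of smallest rings (SSSR) and
#' whether it qualifies as a macrocycle. A macrocycle is defined as a ring of
#' at least 12 heavy atoms; fused systems report their largest SSSR member
#' ring.
#'
#' @param record A `MoleculeRecord` from [parse_structure()].
#' @return A list with `largest_ring_size` (0 for acyclic molecules) and
#'   `is_macrocycle`.
#' @examples
#' detect_macrocycle(parse_structure("c1ccccc1", "benzene"))
#' @export
detect_macrocycle <- function(record) {
  stopifnot(inherits(record, "MoleculeRecord"))
  list(largest_ring_size = record$largest_ring_size,
       is_macrocycle = record$is_macrocycle)
}

# Charge changes of the pH-7 rule-based protonation model applied to a
# molecular graph; returns an integer charge delta per atom. All rules only
# fire on neutral centres, so the model is idempotent by construction.
.ph7_charge_delta <- function(mol) {
  delta <- integer(length(mol$elements))
  plus <- union(.basic_amine_atoms(mol), .amidinium_sites(mol))
  minus <- Reduce(union, list(.acidic_oh_atoms(mol),
                              .tetrazole_nh_atoms(mol),
                              .acylsulfonamide_nh_atoms(mol)))
  delta[plus] <- delta[plus] + 1L
  delta[minus] <- delta[minus] - 1L
  delta
}

#' Assign the major charge state at pH 7.0
#'
#' Applies a deterministic, rule-based protonation model to the neutral
#' structure: aliphatic amines, amidines and guanidines gain a proton
#' (+1 per basic centre); carboxylic, sulfonic and phosphonic/phosphoric
#' acids, acylsulfonamides and tetrazoles lose one. Phenols, alcohols,
#' amides, anilines and pyridines are left unchanged. Unrecognised groups
#' stay neutral. The heavy-atom skeleton is untouched; only formal charges
#' and hydrogen counts change.
#'
#' @param record A `MoleculeRecord` (metal-free).
#' @return The record with `smiles_ph7`, `sdf_ph7` and `mol_ph7` filled in.
#' @examples
#' rec <- protonate_ph7(parse_structure("CCNCC", "diethylamine"))
#' rec$smiles_ph7
#' @export
protonate_ph7 <- function(record) {
  stopifnot(inherits(record, "MoleculeRecord"))
  if (record$contains_metal) {
    stop("protonation rules require a metal-free organic structure (record '",
         record$id, "')", call. = FALSE)
  }
  mol <- record$mol_neutral
  delta <- .ph7_charge_delta(mol)
  sdf <- record$sdf_neutral
  ab <- ChemmineR::atomblock(sdf)
  if (!"C6" %in% colnames(ab)) {
    ab <- cbind(ab, C6 = 0)
  }
  ab[, "C6"] <- .code_from_charge(mol$charge + delta)
  sdf@atomblock <- ab
  record$sdf_ph7 <- sdf
  record$mol_ph7 <- .build_mol(sdf)
  record$smiles_ph7 <- .to_smiles(sdf, record$id)
  record
}

# Resolve the molecular graph for a requested charge state, protonating on
# the fly when needed.
.resolve_mol <- function(record, charge_state = c("ph7", "neutral")) {
  charge_state <- match.arg(charge_state)
  if (charge_state == "neutral") return(record$mol_neutral)
  if (is.null(record$mol_ph7)) record <- protonate_ph7(record)
  record$mol_ph7
}
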