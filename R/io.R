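# File formats and pipeline orchestration: SMILES (.smi) and CSV compound
# tables in, descriptor/prediction tables with reproducibility metadata
# headers out, and a run_pipeline() driver tying the stages together.

#' Read a SMILES file into molecule records
#'
#' One record per line, `SMILES<tab>id` (whitespace-separated); lines
#' starting with `#` and blank lines are skipped. Records without an id get
#' sequential ones.
#'
#' @param path Path to a `.smi` file.
#' @return A list of `MoleculeRecord`s.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[ \t]+")[[1]]
    id <- if (length(parts) >= 2) parts[2] else sprintf("mol_%04d", i)
    out[[i]] <- parse_structure(parts[1], id = id)
  }
  out
}

#' Read a labelled compound table
#'
#' CSV with required columns `id` and `smiles` and optional `name`,
#' `route` (`oral`/`parenteral`) and `origin`.
#'
#' @param path Path to a CSV file.
#' @return A list of `MoleculeRecord`s carrying the labels.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    parse_structure(df$smiles[i], id = as.character(df$id[i]),
                    name = if ("name" %in% names(df)) df$name[i] else
                      as.character(df$id[i]),
                    route = if ("route" %in% names(df) && !is.na(df$route[i]))
                      df$route[i] else "unknown",
                    origin = if ("origin" %in% names(df)) df$origin[i] else
                      NA_character_)
  })
}

#' Write a table with a reproducibility metadata header
#'
#' Prepends `# key: value` comment lines (tool version, dialect switches,
#' seed, ...) to a CSV so every output records how it was produced; floats
#' are kept at full precision.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return Invisibly, `path`.
#' @export
write_table_with_meta <- function(df, path, meta = list()) {
  meta <- c(list(tool = "macrospace",
                 version = as.character(utils::packageVersion("macrospace"))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_with_meta()]
#'
#' @param path Path to the CSV.
#' @return A `data.frame` with the parsed header in `attr(, "meta")`.
#' @export
read_table_with_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  attr(df, "meta") <- meta
  df
}

#' Run the analysis pipeline
#'
#' Executes the requested stages on either a simulated population or parsed
#' structures: `profile` (descriptor table), `derive` (cutoffs and ranked
#' bi-descriptor models from labelled data), `classify` (apply the best or
#' a supplied model), `chemspace` (PCA map). All artifacts are written
#' under `out_dir` together with a machine-readable JSON run manifest
#' recording versions, dialect switches, the seed, row counts and warnings;
#' on stage failure the manifest records the failed stage and partial
#' outputs are retained.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries:
#'   `out_dir` (required); one of `simulate` (a [generator_config()] or
#'   `TRUE` for defaults) or `input` (a `.smi` or `.csv` path);
#'   optional `stages` (default `c("profile", "derive", "classify",
#'   "chemspace")` for simulated/labelled input), `charge_state`,
#'   `exclude_amide`, `model` (path to a model JSON), `seed`,
#'   `descriptors` (for derive/chemspace).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configuration requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  charge_state <- config$charge_state %||% "ph7"
  exclude_amide <- config$exclude_amide %||% TRUE
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("profile", "derive", "classify", "chemspace")
  manifest <- list(
    tool = "macrospace",
    version = as.character(utils::packageVersion("macrospace")),
    charge_state = charge_state,
    nrotb_dialect = if (exclude_amide) "amide-excluded" else "all-single-bonds",
    seed = seed, stages = stages, status = "running",
    warnings = character(0), artifacts = character(0)
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  add_artifact <- function(p) manifest$artifacts <<- c(manifest$artifacts, p)
  current_stage <- "input"
  result <- withCallingHandlers(
    tryCatch({
      table <- if (!is.null(config$simulate)) {
        gc_ <- if (inherits(config$simulate, "GeneratorConfig")) {
          config$simulate
        } else {
          generator_config(seed = seed)
        }
        tab <- generate_labelled_table(gc_)
        manifest$n_compounds <- nrow(tab)
        tab
      } else if (!is.null(config$input)) {
        records <- if (grepl("\\.smi$", config$input)) {
          read_smiles_file(config$input)
        } else {
          read_compound_table(config$input)
        }
        manifest$n_compounds <- length(records)
        current_stage <- "profile"
        descriptor_table(records, charge_state = charge_state,
                         exclude_amide = exclude_amide)
      } else {
        stop("config needs either 'simulate' or 'input'", call. = FALSE)
      }
      if ("profile" %in% stages) {
        current_stage <- "profile"
        p <- file.path(out_dir, "descriptors.csv")
        write_table_with_meta(table, p,
                              list(charge_state = charge_state,
                                   nrotb_dialect = manifest$nrotb_dialect,
                                   seed = seed))
        add_artifact(p)
      }
      derived <- NULL
      if ("derive" %in% stages && "route" %in% names(table) &&
          all(c("oral", "parenteral") %in% table$route)) {
        current_stage <- "derive"
        descs <- config$descriptors %||%
          intersect(c("HBD", "MW", "cLogP", "TPSA"), names(table))
        derived <- enumerate_models(table, descs, order = 2)
        p <- file.path(out_dir, "cutoffs.json")
        jsonlite::write_json(
          lapply(derived$cutoffs, function(co) {
            list(descriptor = co$descriptor, cutoff = co$cutoff,
                 direction = co$direction,
                 raw_intersection = co$raw_intersection)
          }), p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
        add_artifact(p)
        p2 <- file.path(out_dir, "model_ranking.csv")
        write_table_with_meta(derived$ranking, p2, list(seed = seed))
        add_artifact(p2)
      }
      if ("classify" %in% stages) {
        current_stage <- "classify"
        model <- if (!is.null(config$model)) {
          mj <- jsonlite::read_json(config$model, simplifyVector = TRUE)
          do.call(rule_model, lapply(seq_len(nrow(mj$conditions)), function(i) {
            as.list(mj$conditions[i, ])
          }))
        } else if (!is.null(derived)) {
          derived$models[[1]]
        } else {
          stop("classify stage needs a 'model' or a preceding derive stage",
               call. = FALSE)
        }
        pred <- apply_rule(table, model)
        out <- cbind(table[, intersect(c("id", "route"), names(table)),
                           drop = FALSE],
                     predicted = pred)
        p <- file.path(out_dir, "predictions.csv")
        write_table_with_meta(out, p, list(seed = seed))
        add_artifact(p)
        if ("route" %in% names(table) &&
            all(c("oral", "parenteral") %in% table$route)) {
          met <- classifier_metrics(confusion(pred, table$route))
          p3 <- file.path(out_dir, "metrics.json")
          jsonlite::write_json(as.list(met), p3, auto_unbox = TRUE,
                               pretty = TRUE, digits = NA)
          add_artifact(p3)
        }
      }
      if ("chemspace" %in% stages) {
        current_stage <- "chemspace"
        descs <- intersect(c("MW", "cLogP", "cLogS", "TPSA", "HBD", "HBA",
                             "NRotB"), names(table))
        labels <- if ("route" %in% names(table)) table$route else NULL
        map <- pca_map(table, descs, labels = labels,
                       mw_cap = config$mw_cap %||% NULL)
        p <- file.path(out_dir, "pca_scores.csv")
        write_table_with_meta(
          data.frame(id = table$id[seq_len(nrow(map$scores))],
                     map$scores[, 1:2, drop = FALSE]),
          p, list(seed = seed))
        add_artifact(p)
        p4 <- file.path(out_dir, "pca_loadings.csv")
        write_table_with_meta(
          data.frame(descriptor = rownames(map$loadings),
                     map$loadings[, 1:2, drop = FALSE]),
          p4, list(seed = seed))
        add_artifact(p4)
      }
      manifest$status <- "ok"
      table
    }, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- current_stage
      manifest$error <<- conditionMessage(e)
      write_manifest()
      stop(e)
    }),
    warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
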