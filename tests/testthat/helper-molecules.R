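# Memoised structure parsing so repeatedly used records are built once per
# test run.

.rec_cache <- new.env(parent = emptyenv())

rec <- function(smiles, id = smiles) {
  key <- paste(smiles, id, sep = "\r")
  if (is.null(.rec_cache[[key]])) {
    .rec_cache[[key]] <- parse_structure(smiles, id = id)
  }
  .rec_cache[[key]]
}

# a small drug-like panel exercising amines, acids, aromatics, heterocycles
DRUGLIKE_SMILES <- c(
  aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
  ibuprofen    = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
  propranolol  = "CC(C)NCC(O)COc1cccc2ccccc12",
  sulfapyridine = "Nc1ccc(S(=O)(=O)Nc2ccccn2)cc1",
  histamine    = "NCCc1c[nH]cn1",
  metformin    = "CN(C)C(=N)NC(N)=N",
  indomethacin_frag = "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1",
  serotonin    = "NCCc1c[nH]c2ccc(O)cc12",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  glycine      = "NCC(=O)O",
  tyramine     = "NCCc1ccc(O)cc1",
  niacin       = "OC(=O)c1cccnc1"
)
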