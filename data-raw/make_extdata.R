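# Materializes the packaged fixtures under inst/extdata from the
# deterministic generator. Run from the package root after changing the
# generator; the test suite asserts that the packaged files and the
# generator stay in sync.
library(allelemir)

fx <- make_mica_like_fixture()
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# synthetic reference transcript (stand-in for the real MICA mRNA record)
seqs <- Biostrings::DNAStringSet(fx$reference$sequence)
names(seqs) <- sprintf("%s synthetic cds_start=%d end_exclusive=%d",
                       fx$reference$id, fx$reference$cds_start,
                       fx$reference$end_exclusive)
Biostrings::writeXStringSet(seqs, "inst/extdata/synthetic_mica_reference.fasta",
                            width = 70)

# variant TSV (Table-1 transcription)
v <- fx$variants
tsv <- data.frame(
  rsid = v$rsid,
  position = v$position,
  kind = v$kind,
  ref = v$ref,
  alts = vapply(v$alts, paste, "", collapse = ","),
  freqs = vapply(v$freqs, function(f)
    paste(sprintf("%s=%.4f", names(f), f), collapse = ";"), ""),
  ancestral = v$ancestral,
  introduced = v$introduced
)
readr::write_tsv(tsv, "inst/extdata/mica_variants.tsv", progress = FALSE)

# haplotype configuration YAML
cfg <- fx$config
edits_to_yaml <- function(e) {
  list(position = as.integer(e$position), kind = as.character(e$kind),
       ref = as.character(e$ref), alt = as.character(e$alt))
}
yaml_cfg <- list(
  min_freq = cfg$min_freq,
  haplotypes = lapply(cfg$haplotypes, as.list),
  length_classes = as.list(cfg$length_classes),
  subtype_overrides = as.list(cfg$subtype_overrides),
  group_names = as.list(cfg$group_names),
  lineages = as.list(cfg$lineages),
  indels = lapply(cfg$indels, edits_to_yaml),
  lineage_edits = lapply(cfg$lineage_edits, edits_to_yaml)
)
yaml::write_yaml(yaml_cfg, "inst/extdata/mica_haplotypes.yaml")
cat("wrote inst/extdata fixtures\n")
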