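#' Edit table for one haplotype under a pipeline configuration
#'
#' Combines a haplotype's SNP allele assignments (edits where the assigned
#' allele differs from the reference) with the indel of its length class
#' and, optionally, its lineage marker substitutions.
#'
#' @param variants a `variant_table` (the full, unfiltered table).
#' @param config configuration list with `haplotypes`, `length_classes`,
#'   `indels`, `lineages`, `lineage_edits` (see
#'   [make_mica_like_fixture()] / [load_haplotype_config()]).
#' @param label haplotype label.
#' @param lineage_markers include lineage marker substitutions.
#' @return an edit tibble for [apply_haplotype()].
#' @export
haplotype_edit_table <- function(variants, config, label,
                                 lineage_markers = FALSE) {
  if (!label %in% names(config$haplotypes)) {
    abort(sprintf("unknown haplotype label %s", label))
  }
  assign <- config$haplotypes[[label]]
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    al <- assign[[variants$rsid[i]]]
    if (!is.null(al) && !is.na(al) && al != variants$ref[i]) {
      rows[[length(rows) + 1]] <- tibble(position = variants$position[i],
                                         kind = variants$kind[i],
                                         ref = variants$ref[i], alt = al)
    }
  }
  cls <- config$length_classes[[label]]
  ind <- config$indels[[cls]]
  if (!is.null(ind) && nrow(ind) > 0) rows[[length(rows) + 1]] <- as_tibble(ind)
  if (lineage_markers && !is.null(config$lineages)) {
    le <- config$lineage_edits[[config$lineages[[label]]]]
    if (!is.null(le) && nrow(le) > 0) rows[[length(rows) + 1]] <- as_tibble(le)
  }
  if (length(rows) == 0) {
    return(tibble(position = integer(), kind = character(),
                  ref = character(), alt = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$position)
}

#' Run the full allele-aware miRNA binding pipeline
#'
#' Executes build -> classify -> scan -> energy -> impact -> fold /
#' accessibility -> tree on one configuration and (optionally) writes all
#' per-stage tables plus a JSON run manifest. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config a list with:
#'   * `reference`: a `ref_transcript`, or a list `(path, cds_start,
#'     end_exclusive)` pointing at a FASTA;
#'   * `variants`: a `variant_table` or a TSV path;
#'   * `haplotypes`: a configuration list (see [load_haplotype_config()] /
#'     [make_mica_like_fixture()]) or a YAML path;
#'   * `mirnas`: a tibble (`mirna_id`, `sequence`) or a FASTA path; may be
#'     empty;
#'   * `out_dir`: output directory (NULL to skip writing);
#'   * `min_freq` (default from the haplotype config, else 0.005),
#'     `energy_threshold` (default -8.00 kcal/mol), `flank` (default 16),
#'     `fold` and `tree` switches (default TRUE), `seed` (default 1,
#'     recorded in the manifest; all pipeline stages are deterministic).
#' @return (invisibly) a report bundle: a list with every stage table, the
#'   fold results, the tree, and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  ref <- cfg$reference
  if (!inherits(ref, "ref_transcript")) {
    ref <- read_reference_fasta(ref$path, ref$cds_start, ref$end_exclusive)
  }
  variants <- cfg$variants
  input_files <- character()
  if (is.character(variants)) {
    input_files <- c(input_files, variants = variants)
    variants <- load_variant_table(variants)
  }
  hcfg <- cfg$haplotypes
  if (is.character(hcfg)) {
    input_files <- c(input_files, haplotypes = hcfg)
    hcfg <- load_haplotype_config(hcfg)
  }
  mirnas <- cfg$mirnas %||% tibble(mirna_id = character(),
                                   sequence = character())
  if (is.character(mirnas)) {
    input_files <- c(input_files, mirnas = mirnas)
    mirnas <- read_mirna_fasta(mirnas)
  }
  min_freq <- cfg$min_freq %||% hcfg$min_freq %||% 0.005
  threshold <- cfg$energy_threshold %||% -8.00
  flank <- cfg$flank %||% 16
  params <- cfg$params %||% turner_params()
  seed <- cfg$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  filt <- stage("filter", filter_by_frequency(variants, min_freq))
  types <- stage("classify", classify_utr_types(
    filt$retained, hcfg$haplotypes, hcfg$length_classes,
    hcfg$subtype_overrides, hcfg$group_names,
    known_rsids = variants$rsid))

  utrs <- stage("build", {
    us <- lapply(seq_len(nrow(types)), function(i) {
      rep_member <- types$members[[i]][1]
      edits <- haplotype_edit_table(variants, hcfg, rep_member)
      build_allele_utr(ref, edits, types$name[i])
    })
    stats::setNames(us, types$name)
  })

  sites <- stage("scan", scan_all_sites(mirnas, utrs, filt$retained))
  energies <- stage("energy", site_duplex_energies(
    sites, mirnas, utrs, params, flank, threshold))

  impact_snp <- stage("impact", pipeline_snp_impacts(
    energies, types, variants, mirnas, threshold))
  impact_pairs <- stage("impact", pipeline_pair_impacts(
    energies, types, mirnas))

  folds <- NULL
  access <- empty_accessibility()
  if (isTRUE(cfg$fold %||% TRUE)) {
    folds <- stage("fold", {
      fs <- lapply(utrs, function(u) fold_utr(u$utr_sequence, params))
      stats::setNames(fs, names(utrs))
    })
    access <- stage("fold", pipeline_accessibility(folds, energies))
  }

  tree <- NULL
  distances <- NULL
  if (isTRUE(cfg$tree %||% TRUE) && nrow(types) >= 3) {
    tree_seqs <- stage("tree", {
      vapply(seq_len(nrow(types)), function(i) {
        rep_member <- types$members[[i]][1]
        edits <- haplotype_edit_table(variants, hcfg, rep_member,
                                      lineage_markers = TRUE)
        apply_haplotype(ref, edits)$sequence
      }, "") |> stats::setNames(types$name)
    })
    tr <- stage("tree", utr_tree(tree_seqs))
    tree <- tr$tree
    distances <- tr$distances
  }

  manifest <- list(
    package = "allelemir",
    version = as.character(utils::packageVersion("allelemir")),
    seed = seed,
    settings = list(min_freq = min_freq, energy_threshold = threshold,
                    flank = flank, fold = isTRUE(cfg$fold %||% TRUE),
                    tree = isTRUE(cfg$tree %||% TRUE)),
    reference = list(id = ref$id, length = nchar(ref$sequence),
                     cds_start = ref$cds_start,
                     end_exclusive = ref$end_exclusive),
    n_variants = nrow(variants), n_retained = nrow(filt$retained),
    excluded = filt$excluded,
    utr_types = types$name,
    n_mirnas = nrow(mirnas),
    input_md5 = if (length(input_files) > 0) {
      as.list(tools::md5sum(unname(input_files))) |>
        stats::setNames(names(input_files))
    } else list()
  )

  bundle <- list(reference = ref, variants = variants, retained = filt$retained,
                 excluded = filt$excluded, types = types, utrs = utrs,
                 mirnas = mirnas, sites = sites, energies = energies,
                 impact_snp = impact_snp, impact_pairs = impact_pairs,
                 folds = folds, accessibility = access, tree = tree,
                 distances = distances, manifest = manifest,
                 threshold = threshold)
  class(bundle) <- "allelemir_report"

  if (!is.null(cfg$out_dir)) write_report(bundle, cfg$out_dir)
  invisible(bundle)
}

empty_accessibility <- function() {
  tibble(mirna_id = character(), utr_label = character(), t1 = integer(),
         site_type = character(), start_nt = integer(),
         start_nt_unpaired_in_mfe = logical(), mean_unpaired_prob = double(),
         accessible = logical())
}

# gain/loss calls for every UTR-type pair differing at exactly one retained
# variant, oriented ancestral -> derived by the table's ancestral allele
pipeline_snp_impacts <- function(energies, types, variants, mirnas,
                                 threshold) {
  out <- list()
  n <- nrow(types)
  anc <- stats::setNames(variants$ancestral, variants$rsid)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (j > n) break
      ai <- types$assignments[[i]]
      aj <- types$assignments[[j]]
      diff <- names(ai)[ai[names(ai)] != aj[names(ai)]]
      if (length(diff) != 1) next
      rsid <- diff
      # orientation: the side carrying the ancestral allele is ancestral
      if (ai[[rsid]] == anc[[rsid]]) {
        lab_a <- types$name[i]; lab_d <- types$name[j]
        asg_a <- ai; asg_d <- aj
      } else {
        lab_a <- types$name[j]; lab_d <- types$name[i]
        asg_a <- aj; asg_d <- ai
      }
      ea <- energies[energies$utr_label == lab_a, ]
      ed <- energies[energies$utr_label == lab_d, ]
      for (m in mirnas$mirna_id) {
        out[[length(out) + 1]] <- call_gain_loss(
          ea, ed, m, rsid, threshold,
          assignments_anc = asg_a, assignments_der = asg_d,
          utr_pair = c(lab_a, lab_d))
      }
    }
  }
  if (length(out) == 0) {
    tibble(mirna_id = character(), rsid = character(),
           utr_ancestral = character(), utr_derived = character(),
           mfe_ancestral = double(), mfe_derived = double(),
           delta_mfe = double(), call = character())
  } else dplyr::bind_rows(out)
}

# Table-3-style pairwise UTR-type deltas from the computed energies
pipeline_pair_impacts <- function(energies, types, mirnas) {
  best <- energies |>
    dplyr::filter(.data$passes, is.finite(.data$energy)) |>
    dplyr::group_by(.data$mirna_id, .data$utr_label) |>
    dplyr::summarise(mfe = min(.data$energy, Inf), .groups = "drop")
  out <- list()
  n <- nrow(types)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (j > n) break
      la <- types$name[i]; lb <- types$name[j]
      for (m in mirnas$mirna_id) {
        ma <- best$mfe[best$mirna_id == m & best$utr_label == la]
        mb <- best$mfe[best$mirna_id == m & best$utr_label == lb]
        ma <- if (length(ma) == 1) ma else NA_real_
        mb <- if (length(mb) == 1) mb else NA_real_
        if (!is.finite(ma) && !is.finite(mb)) next
        call <- if (is.finite(ma) && is.finite(mb)) "both"
                else if (is.finite(ma)) "only_a" else "only_b"
        out[[length(out) + 1]] <- tibble(
          mirna_id = m, utr_a = la, utr_b = lb, mfe_a = ma, mfe_b = mb,
          delta_mfe = delta_mfe(ma, mb), call = call)
      }
    }
  }
  if (length(out) == 0) {
    tibble(mirna_id = character(), utr_a = character(), utr_b = character(),
           mfe_a = double(), mfe_b = double(), delta_mfe = double(),
           call = character())
  } else dplyr::bind_rows(out)
}

pipeline_accessibility <- function(folds, energies) {
  pass <- energies[energies$passes, ]
  if (nrow(pass) == 0) return(empty_accessibility())
  rows <- lapply(seq_len(nrow(pass)), function(i) {
    f <- folds[[pass$utr_label[i]]]
    acc <- accessibility(f, pass[i, ])
    dplyr::bind_cols(pass[i, c("mirna_id", "utr_label", "t1", "site_type")],
                     acc)
  })
  dplyr::bind_rows(rows)
}

#' Per-miRNA summary of a report bundle
#'
#' For each miRNA with at least one threshold-passing site: the number of
#' UTR types bound, the best (lowest) energy, and the site multiplicity
#' (largest number of passing sites on any single UTR type).
#'
#' @param bundle an `allelemir_report` from [run_pipeline()].
#' @return a tibble with one row per miRNA.
#' @export
summarize_report <- function(bundle) {
  pass <- bundle$energies[bundle$energies$passes, ]
  if (nrow(pass) == 0) {
    return(tibble(mirna_id = character(), utr_types_bound = integer(),
                  best_energy = double(), site_multiplicity = integer()))
  }
  pass |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(
      utr_types_bound = dplyr::n_distinct(.data$utr_label),
      best_energy = min(.data$energy),
      site_multiplicity = max(table(.data$utr_label)),
      .groups = "drop") |>
    dplyr::mutate(site_multiplicity = as.integer(.data$site_multiplicity))
}

#' @export
print.allelemir_report <- function(x, ...) {
  cat("<allelemir_report>\n")
  cat(sprintf("  %d variants (%d retained), %d UTR types, %d miRNAs\n",
              nrow(x$variants), nrow(x$retained), nrow(x$types),
              nrow(x$mirnas)))
  cat(sprintf("  %d seed sites, %d passing energies (threshold %.2f)\n",
              nrow(x$sites), sum(x$energies$passes), x$threshold))
  invisible(x)
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  flat_variants <- bundle$retained |>
    dplyr::mutate(
      alts = vapply(.data$alts, paste, "", collapse = ","),
      freqs = vapply(.data$freqs, function(f)
        paste(sprintf("%s=%.4f", names(f), f), collapse = ";"), "")) |>
    as_tibble()
  readr::write_tsv(flat_variants, p("variants_retained.tsv"), progress = FALSE)
  readr::write_tsv(tibble(excluded_rsid = bundle$excluded), p("excluded.tsv"),
                   progress = FALSE)
  readr::write_tsv(utr_type_matrix(bundle$types), p("utr_types.tsv"),
                   progress = FALSE)
  readr::write_tsv(utr_table(bundle$utrs), p("allele_utrs.tsv"),
                   progress = FALSE)
  write_utr_fasta(bundle$utrs, p("utrs.fasta"))
  sites_flat <- bundle$sites |>
    dplyr::mutate(overlapped_rsids = vapply(.data$overlapped_rsids, paste, "",
                                            collapse = ","))
  readr::write_tsv(sites_flat, p("sites.tsv"), progress = FALSE)
  energies_flat <- bundle$energies |>
    dplyr::mutate(
      overlapped_rsids = vapply(.data$overlapped_rsids, paste, "",
                                collapse = ","),
      energy_kcal_mol = ifelse(is.na(.data$energy), "",
                               sprintf("%.2f", .data$energy)))
  readr::write_tsv(energies_flat, p("energies.tsv"), progress = FALSE)
  snp_flat <- bundle$impact_snp |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ round(.x, 6)))
  readr::write_tsv(snp_flat, p("impact_snp.tsv"), progress = FALSE)
  readr::write_tsv(bundle$impact_pairs, p("impact_utr_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$accessibility, p("accessibility.tsv"),
                   progress = FALSE)
  if (!is.null(bundle$folds)) {
    for (nm in names(bundle$folds)) {
      write_vienna(bundle$folds[[nm]], p(sprintf("fold_%s.dbn", nm)), nm)
      write_bpp_tsv(bundle$folds[[nm]], p(sprintf("bpp_%s.tsv", nm)))
    }
  }
  if (!is.null(bundle$tree)) {
    ape::write.tree(bundle$tree, p("tree.nwk"))
    dm <- as_tibble(bundle$distances, rownames = "utr_type")
    readr::write_tsv(dm, p("distances.tsv"), progress = FALSE)
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
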