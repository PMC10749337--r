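# shared fixtures, built once per test run

mica_fx <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_mica_like_fixture()
    fx
  }
})

mica_utrs <- local({
  utrs <- NULL
  function() {
    if (is.null(utrs)) {
      fx <- mica_fx()
      reps <- c(UTR1a = "*008", UTR1b = "*004", UTR1c = "*010",
                UTR2a = "*002", UTR2b = "*007", UTR2c = "*015",
                UTR4 = "*001", UTR7 = "*011")
      utrs <<- stats::setNames(lapply(names(reps), function(ty) {
        build_allele_utr(fx$reference,
                         haplotype_edit_table(fx$variants, fx$config,
                                              reps[[ty]]),
                         ty)
      }), names(reps))
    }
    utrs
  }
})

rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

test_params <- turner_params()
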