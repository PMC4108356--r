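# the seven published per-class parameter sets used across tests
ref_classes <- jalapao_classes()

# independent brute-force mean interval: direct survival sum via pnorm only
brute_mean <- function(ml, sl, tmax = 2e5) {
  1 + sum(pnorm((log(seq_len(tmax)) - ml) / sl, lower.tail = FALSE))
}

# a small deterministic mixed interval sample
mixed_sample <- function() {
  data.frame(
    length = c(2L, 3L, 1L, 5L, 2L, 4L, 0L, 3L, 1L, 6L),
    status = c("complete", "complete", "complete", "complete", "complete",
               "right_censored", "right_censored", "left_censored",
               "left_censored", "right_censored"),
    stringsAsFactors = FALSE
  )
}
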