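# Shared fixtures, built in code at test time.

toy_panel <- function() {
  GlycanPanel("toy3", c("P1", "P2", "P3"),
              list(derivedTraitDef("X", c("P1", "P2")),
                   derivedTraitDef("Y", c("P3"))))
}

# minimal normalized table: features x samples
toy_table <- function(mat, state = "normalized", panel = NULL, ...) {
  extra <- list(...)
  sd <- data.frame(sample_id = paste0("s", seq_len(ncol(mat))))
  for (nm in names(extra)) sd[[nm]] <- extra[[nm]]
  ge <- GlycanExperiment(mat, sd, panel = panel, state = state)
  ge
}

# a 6-feature two-batch log-scale table with a known pure location shift
shifted_log_table <- function(n_per_batch = 200, shift = seq(0.5, 1.5,
                                                            length.out = 6),
                              seed = 42) {
  set.seed(seed)
  G <- length(shift)
  Y <- matrix(rnorm(G * 2 * n_per_batch, mean = 2, sd = 0.3), G,
              2 * n_per_batch)
  Y[, (n_per_batch + 1):(2 * n_per_batch)] <-
    Y[, (n_per_batch + 1):(2 * n_per_batch)] + shift
  rownames(Y) <- paste0("F", seq_len(G))
  ge <- toy_table(Y, state = "log",
                  plate_id = rep(c("b1", "b2"), each = n_per_batch))
  list(table = ge, shift = shift, n = n_per_batch)
}

# reference-composition single measurement as a normalized table
reference_table <- function(standard = 4, panel = loadPanel("cge_lif_27")) {
  comp <- referenceComposition(standard)
  mat <- matrix(comp, ncol = 1, dimnames = list(names(comp), "ref"))
  toy_table(mat, panel = panel)
}

# swap-injection helper: pick a random pair whose baseline G0 differs by
# more than `margin` of the smaller value, then swap at `day`
inject_conspicuous_swaps <- function(co, n_swaps, day, margin = 0.09,
                                     seed = 1) {
  set.seed(seed)
  cd <- SummarizedExperiment::colData(co)
  mat <- SummarizedExperiment::assay(co)
  g0_peaks <- c("GP14", "GP15", "GP18")
  present <- unique(cd$subject_id[cd$time_days == day])
  g0 <- vapply(present, function(s) {
    j <- which(cd$subject_id == s & cd$time_days == 0)
    sum(mat[g0_peaks, j])
  }, numeric(1))
  used <- character()
  for (k in seq_len(n_swaps)) {
    repeat {
      pr <- sample(setdiff(present, used), 2)
      if (abs(g0[pr[1]] - g0[pr[2]]) > margin * min(g0[pr])) break
    }
    used <- c(used, pr)
    co <- injectSampleSwap(co, pr[1], pr[2], day)
  }
  co
}
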