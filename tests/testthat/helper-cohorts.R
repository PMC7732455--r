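# small deterministic cohorts used across tests

tinyConfig <- function(seed = 1L, n_participants = 9,
                       followup_split = c(3, 3, 3), n_proteins = 40, ...) {
  simConfig(n_participants = n_participants,
            followup_split = followup_split,
            n_proteins = n_proteins, seed = seed, ...)
}

# clean cohort: no censoring, no batch effects, no RNA/Ig unless asked
cleanConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(censor_quantile = 0,
                   batch_effects = data.frame(shift = 0, scale = 1),
                   ig_panel = NULL, n_genes = 0, seed = seed)
  defaults[names(args)] <- args
  do.call(simConfig, defaults)
}

# global-null cohort: flat proteins only
nullConfig <- function(seed = 1L, n_proteins = 200, n_participants = 30,
                       followup_split = c(10, 10, 10), ...) {
  cleanConfig(seed = seed, n_proteins = n_proteins,
              n_participants = n_participants,
              followup_split = followup_split,
              trajectory_classes = list(flat = list(fraction = 1)), ...)
}

# hand-built paired metadata: n participants per follow-up day
pairedMeta <- function(n1 = 3, n3 = 3, n7 = 3) {
  fup <- rep(c(1L, 3L, 7L), c(n1, n3, n7))
  pid <- sprintf("P%02d", seq_along(fup))
  data.frame(
    sample_id = c(paste0(pid, "_D0"), paste0(pid, "_D", fup)),
    participant_id = c(pid, pid),
    dol = c(rep(0L, length(pid)), fup),
    sex = "F", batch = "B1", cohort = "test",
    stringsAsFactors = FALSE)
}

# build a ProteinQuantExperiment from a bare matrix + paired meta
quickPQE <- function(m, meta, ibaq = NULL) {
  colnames(m) <- meta$sample_id
  ProteinQuantExperiment(m, meta, ibaq = ibaq)
}

# independent two-sided Fisher oracle by hypergeometric enumeration
fisherOracle <- function(a, b, c, d) {
  k <- a + c                      # total detected
  n1 <- a + b; n2 <- c + d
  lo <- max(0, k - n2); hi <- min(k, n1)
  pr <- stats::dhyper(lo:hi, n1, n2, k)
  obs <- stats::dhyper(a, n1, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# O(m^2) definitional BH oracle
bhOracle <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      pj <- p[j]
      if (pj >= p[i]) pj * m / sum(p <= pj) else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
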