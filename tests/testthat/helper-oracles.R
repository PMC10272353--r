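# Shared oracles and small fixtures, independent of the implementation paths
# they are used to check.

# Match detected event times against ground-truth times within a tolerance;
# returns hit rate (fraction of truth matched) and false-discovery proportion.
match_events <- function(detected, truth, tol_s = 5e-4) {
  if (length(detected) == 0)
    return(list(hit_rate = 0, fdp = NA_real_))
  d <- abs(outer(detected, truth, "-"))
  list(hit_rate = mean(apply(d, 2, min) < tol_s),
       fdp = mean(apply(d, 1, min) >= tol_s))
}

# Unit-variance Laplace sampler (inverse CDF).
rlaplace <- function(n) {
  u <- stats::runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# Mean matched absolute correlation between two q x n source matrices,
# maximized over the q! row permutations (exhaustive; q is small).
best_matched_abs_cor <- function(S_est, S_true) {
  q <- nrow(S_true)
  C <- abs(stats::cor(t(S_est), t(S_true)))
  perms <- as.matrix(expand.grid(rep(list(seq_len(q)), q)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == q), ,
                 drop = FALSE]
  max(apply(perms, 1, function(p) mean(C[cbind(p, seq_len(q))])))
}

# Largest principal angle (radians) between the column spans of U and V.
max_principal_angle <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  acos(min(1, max(-1, min(s))))
}

# Small cohort configuration used by several unit tests.
tiny_sim_config <- function(...) {
  sim_config(n_animals = 1, channels_per_area = 2, n_shanks = 1,
             sites_per_shank = 2, n_trials_per_type = 4, rng_seed = 99, ...)
}

# A hand-built Solenoid-only schedule (no ICMS events) for detection tests.
plain_schedule <- function(n_trials, period = 1, pre = 0.25, onset_ms = 50) {
  t_start <- (seq_len(n_trials) - 1) * period
  data.frame(trial = seq_len(n_trials), type = "Solenoid",
             t_start = t_start, t_zero = t_start + pre,
             solenoid_time = t_start + pre + onset_ms / 1000,
             icms_time = NA_real_)
}
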