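# Shared fixtures: small simulated data sets built in code.

# a simulated response set from a known scale
sim_responses <- function(n_trials, sigma, psi = seq(0, 1, length.out = 10),
                          seed = 1, lapse = 0) {
  tr <- sample_triplet_trials(length(psi), n_trials, seed = seed)
  simulate_triplet_responses(tr, psi, sigma = sigma, lapse = lapse,
                             seed = seed + 1000L)
}

# independent brute-force continuum selection: enumerate all index subsets
brute_force_continuum <- function(d, k) {
  m <- length(d)
  Tspan <- max(d)
  target <- seq_len(k) * Tspan / k
  best <- NULL
  for (sub in utils::combn(m, k, simplify = FALSE)) {
    ds <- d[sub]
    if (any(diff(ds) < 0)) next
    val <- sum((ds - target)^2)
    if (is.null(best) || val < best$val - 1e-12) best <- list(val = val, idx = sub)
  }
  best
}

# independent anchor/guide search over all (anchor, guide) pairs
brute_force_anchor_guide <- function(D) {
  n <- nrow(D)
  means <- sapply(seq_len(n), function(i) mean(D[i, -i]))
  anchor <- unname(which(means == min(means))[1])
  d <- unname(D[anchor, ])
  d[anchor] <- Inf
  guide <- which(d == min(d))[1]
  list(anchor = anchor, guide = guide)
}

# independent foil search: all 3-subsets of the 9 non-target images
brute_force_foils <- function(psi) {
  target <- which(psi == 0)
  cand <- setdiff(seq_along(psi), target)
  span <- max(abs(psi[cand] - psi[target]))
  ladder <- 1:3 * span / 3
  best <- NULL
  for (sub in utils::combn(cand, 3, simplify = FALSE)) {
    g <- sort(abs(psi[sub] - psi[target]))
    val <- sum((g - ladder)^2)
    if (is.null(best) || val < best$val - 1e-12) best <- list(val = val, idx = sub)
  }
  best
}

# one participant's memory design + simulated responses
sim_memory_participants <- function(n_participants, params = memory_model_params(),
                                    seed = 1) {
  sessions <- lapply(seq_len(n_participants), function(p) {
    generate_memory_session(sprintf("r%02d", 1:9), sprintf("n%02d", 1:54),
                            seed = seed * 1000L + p,
                            participant_id = sprintf("P%03d", p))
  })
  design <- do.call(rbind, lapply(sessions, as.data.frame))
  simulate_memory_responses(design, params, seed = seed)
}

# path-like candidate distances: mostly increasing with local dips, the
# regime interpolation paths live in
path_distances <- function(m) {
  pmax(cumsum(rnorm(m, 0.3, 0.25)), 0.01)
}
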