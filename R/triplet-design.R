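#' Enumerate all triads over n stimuli
#'
#' In the method of triads every trial presents a reference \eqn{s_i} and an
#' unordered probe pair \eqn{\{s_j, s_k\}}. For `n` stimuli there are
#' `n * choose(n - 1, 2)` distinct triads; they are returned in deterministic
#' lexicographic order of `(reference, probe1, probe2)` with `probe1 < probe2`.
#'
#' @param n number of stimuli (>= 3).
#' @return data.frame with integer columns `reference`, `probe1`, `probe2`.
#' @examples
#' nrow(enumerate_triads(10))  # 360
#' @export
enumerate_triads <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != as.integer(n)) {
    stop("`n` must be a single integer >= 3")
  }
  n <- as.integer(n)
  out <- lapply(seq_len(n), function(ref) {
    others <- setdiff(seq_len(n), ref)
    pr <- utils::combn(others, 2)
    data.frame(reference = ref, probe1 = pr[1, ], probe2 = pr[2, ])
  })
  do.call(rbind, out)
}

#' Generate a triplet-judgement session
#'
#' Designs one participant's similarity-judgement session: `n_trials` triads
#' (default 288) in `n_blocks` blocks (default 6 blocks of 48). Trials are
#' distributed as evenly as possible over the requested object sets; within
#' an object, triads are sampled without replacement, stratified so that
#' every image serves as reference equally often (within one trial). For each
#' unordered probe pair the left/right placement of the probes is balanced to
#' within one trial. The fixation jitter is drawn uniformly from
#' 500–1000 ms in 100-ms steps. The whole session is reproducible from
#' `seed`.
#'
#' @param objects character vector of object-set ids covered by the session.
#' @param n_images images per object set (default 10).
#' @param seed integer seed; the session is a pure function of
#'   `(objects, n_images, seed)`.
#' @param participant_id participant label.
#' @param n_trials,n_blocks session shape; `n_trials` must be divisible by
#'   `n_blocks`.
#' @return a `"triplet_session"` data.frame with columns `participant`,
#'   `block`, `trial`, `object`, `reference`, `probe_left`, `probe_right`,
#'   `fixation_ms`.
#' @export
generate_session <- function(objects, n_images = 10, seed,
                             participant_id = "P001",
                             n_trials = 288, n_blocks = 6) {
  if (length(objects) < 1L) stop("need at least one object set")
  objects <- as.character(objects)
  if (anyDuplicated(objects)) stop("object ids must be unique")
  if (n_trials %% n_blocks != 0) stop("`n_trials` must be divisible by `n_blocks`")
  if (n_images < 3) stop("`n_images` must be >= 3")
  set_seed_if(seed)

  triads <- enumerate_triads(n_images)
  n_obj <- length(objects)
  per_ref_total <- choose(n_images - 1, 2)

  # even split of trials over objects; remainder goes to a random subset
  base <- n_trials %/% n_obj
  quota <- rep(base, n_obj)
  rem <- n_trials - base * n_obj
  if (rem > 0) quota[sample.int(n_obj, rem)] <- base + 1
  if (any(quota > nrow(triads))) {
    stop(sprintf(paste0("infeasible design: %d trials over %d object set(s) ",
                        "needs %d triads per object but only %d exist ",
                        "(constraint: no triad repeats within an object)"),
                 n_trials, n_obj, max(quota), nrow(triads)))
  }

  one_object <- function(obj, q) {
    # reference stratification: each image is reference floor(q/n) or
    # ceil(q/n) times
    ref_quota <- rep(q %/% n_images, n_images)
    extra <- q - sum(ref_quota)
    if (extra > 0) ref_quota[sample.int(n_images, extra)] <- ref_quota[1] + 1L
    if (any(ref_quota > per_ref_total)) {
      stop(sprintf(paste0("infeasible design: object '%s' needs %d triads for ",
                          "one reference but only %d exist ",
                          "(constraint: reference stratification +/-1)"),
                   obj, max(ref_quota), per_ref_total))
    }
    rows <- lapply(seq_len(n_images), function(ref) {
      pool <- triads[triads$reference == ref, , drop = FALSE]
      pool[sample.int(nrow(pool), ref_quota[ref]), , drop = FALSE]
    })
    tr <- do.call(rbind, rows)
    tr$object <- obj

    # left/right counterbalance per unordered probe pair: the lower-indexed
    # probe goes left in half the pair's trials (+/- 1), shuffled
    key <- paste(tr$probe1, tr$probe2)
    tr$lower_left <- TRUE
    for (kk in unique(key)) {
      idx <- which(key == kk)
      pattern <- rep(c(TRUE, FALSE), length.out = length(idx))
      tr$lower_left[idx] <- sample(pattern)
    }
    tr$probe_left <- ifelse(tr$lower_left, tr$probe1, tr$probe2)
    tr$probe_right <- ifelse(tr$lower_left, tr$probe2, tr$probe1)
    tr
  }

  all_tr <- do.call(rbind, Map(one_object, objects, quota))
  all_tr <- all_tr[sample.int(nrow(all_tr)), , drop = FALSE]

  session <- data.frame(
    participant = participant_id,
    block = rep(seq_len(n_blocks), each = n_trials / n_blocks),
    trial = seq_len(n_trials),
    object = all_tr$object,
    reference = all_tr$reference,
    probe_left = all_tr$probe_left,
    probe_right = all_tr$probe_right,
    fixation_ms = sample(seq(500L, 1000L, by = 100L), n_trials, replace = TRUE),
    row.names = NULL
  )
  attr(session, "seed") <- seed
  attr(session, "n_images") <- n_images
  class(session) <- c("triplet_session", "data.frame")
  session
}

#' Write/read a triplet session (or response table) as CSV
#' @param session a `"triplet_session"` data.frame.
#' @param path file path.
#' @export
write_triplet_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_triplet_csv
#' @export
read_triplet_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("object", "reference", "probe_left", "probe_right")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("triplet CSV missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Sample triplet trials uniformly from the triad universe
#'
#' Draws `n_trials` triads uniformly with replacement from
#' [enumerate_triads()] and randomizes the left/right probe placement —
#' the quick way to produce arbitrarily large response sets for simulation
#' studies, without the session-level balance constraints of
#' [generate_session()].
#'
#' @param n_images number of stimuli.
#' @param n_trials number of trials to draw.
#' @param seed integer seed.
#' @param object object-set label for the trials.
#' @return data.frame with columns `object`, `reference`, `probe_left`,
#'   `probe_right`.
#' @export
sample_triplet_trials <- function(n_images, n_trials, seed = NULL,
                                  object = "obj") {
  set_seed_if(seed)
  triads <- enumerate_triads(n_images)
  tr <- triads[sample.int(nrow(triads), n_trials, replace = TRUE), , drop = FALSE]
  flip <- stats::runif(n_trials) < 0.5
  data.frame(
    object = object,
    reference = tr$reference,
    probe_left = ifelse(flip, tr$probe2, tr$probe1),
    probe_right = ifelse(flip, tr$probe1, tr$probe2),
    row.names = NULL
  )
}
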