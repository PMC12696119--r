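#' Pairwise perceptual distance matrix
#'
#' Computes a symmetric distance matrix over feature rows with a choice of
#' backend: plain Euclidean, cosine distance (1 minus cosine similarity), or a
#' user-supplied plugin satisfying the distance contract (a function of two
#' feature vectors returning a single nonnegative number). A learned
#' perceptual metric such as LPIPS plugs in through the `plugin` backend; the
#' built-in metrics serve as lightweight stand-ins wherever the pipeline only
#' needs *some* perceptual distance.
#'
#' @param features numeric matrix, one item per row (>= 2 rows).
#' @param metric `"euclidean"`, `"cosine"` or `"plugin"`.
#' @param plugin for `metric = "plugin"`: `function(x, y)` returning a
#'   nonnegative scalar. Both orientations are evaluated and must agree
#'   within `tol`.
#' @param ids item labels; defaults to rownames or `item1..itemn`.
#' @param tol symmetry tolerance for the plugin backend.
#' @return a `"distance_matrix"`: a symmetric numeric matrix with zero
#'   diagonal and ids as dimnames.
#' @export
pairwise_distance <- function(features,
                              metric = c("euclidean", "cosine", "plugin"),
                              plugin = NULL, ids = NULL, tol = 1e-8) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 feature rows")
  if (!is.numeric(features) || !all(is.finite(features))) {
    stop("features must be finite numeric (no NaN/NA/Inf)")
  }
  n <- nrow(features)
  ids <- ids %||% rownames(features) %||% sprintf("item%03d", seq_len(n))

  D <- switch(metric,
    euclidean = as.matrix(stats::dist(features, method = "euclidean")),
    cosine = {
      nrm <- sqrt(rowSums(features^2))
      if (any(nrm == 0)) stop("cosine distance undefined for zero-norm rows")
      S <- (features / nrm) %*% t(features / nrm)
      S[S > 1] <- 1; S[S < -1] <- -1
      1 - S
    },
    plugin = {
      if (!is.function(plugin)) stop("`plugin` must be a function(x, y)")
      M <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          dij <- plugin(features[i, ], features[j, ])
          dji <- plugin(features[j, ], features[i, ])
          if (!is.numeric(dij) || length(dij) != 1L || !is.finite(dij) || dij < 0) {
            stop("plugin metric must return a single nonnegative finite number")
          }
          if (abs(dij - dji) > tol) {
            stop(sprintf("plugin metric asymmetric beyond tolerance at (%d, %d): %g vs %g",
                         i, j, dij, dji))
          }
          M[i, j] <- M[j, i] <- (dij + dji) / 2
        }
      }
      M
    }
  )
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  as_distance_matrix(D)
}

#' Validate and classify a square matrix as a distance matrix
#'
#' @param D square numeric matrix; must be symmetric within `tol`, have a
#'   zero diagonal and nonnegative entries.
#' @param ids optional replacement dimnames.
#' @param tol symmetry/diagonal tolerance.
#' @export
as_distance_matrix <- function(D, ids = NULL, tol = 1e-9) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (!is.numeric(D) || !all(is.finite(D))) stop("distance matrix must be finite numeric")
  if (max(abs(D - t(D))) > tol) stop("distance matrix not symmetric within tolerance")
  if (max(abs(diag(D))) > tol) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be nonnegative")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  if (is.null(dimnames(D))) {
    dimnames(D) <- list(sprintf("item%03d", seq_len(nrow(D))),
                        sprintf("item%03d", seq_len(nrow(D))))
  }
  class(D) <- c("distance_matrix", class(matrix()))
  D
}

#' Read/write a distance matrix as square CSV with id headers
#' @param D a `"distance_matrix"`.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), unclass(D), check.names = FALSE)
  colnames(df) <- c("id", colnames(D))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  as_distance_matrix(M)
}

#' Select the anchor and guide image from a distance matrix
#'
#' The anchor is the medoid: the item with the minimum mean distance to all
#' other items (most representative of the set). The guide is the anchor's
#' nearest neighbour (most perceptually similar to the anchor). Ties are
#' broken by lowest index, making the rule deterministic and auditable.
#'
#' @param D a `"distance_matrix"` with at least 3 items.
#' @return an `"anchor_guide"` list: `anchor_id`, `guide_id`,
#'   `anchor_index`, `guide_index`, `anchor_mean_distance`, `pair_distance`.
#' @export
select_anchor_guide <- function(D) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("anchor/guide selection needs at least 3 items")
  mean_to_others <- rowSums(D) / (n - 1)
  anchor <- unname(which.min(mean_to_others))  # which.min -> lowest index on ties
  d <- D[anchor, ]
  d[anchor] <- Inf
  guide <- unname(which.min(d))
  structure(
    list(anchor_id = rownames(D)[anchor], guide_id = rownames(D)[guide],
         anchor_index = anchor, guide_index = guide,
         anchor_mean_distance = mean_to_others[[anchor]],
         pair_distance = D[anchor, guide]),
    class = "anchor_guide"
  )
}

#' @export
print.anchor_guide <- function(x, ...) {
  cat(sprintf("anchor = %s (mean distance %.4g), guide = %s (pair distance %.4g)\n",
              x$anchor_id, x$anchor_mean_distance, x$guide_id, x$pair_distance))
  invisible(x)
}

#' Select an approximately linear continuum from interpolation candidates
#'
#' Given the perceptual distances of `m` interpolated candidates from the
#' anchor (in path order), chooses `k` candidates whose distances are
#' non-decreasing along the path and as close as possible to the equispaced
#' ladder `j * T / k`, `j = 1..k`, where `T` is the maximum candidate
#' distance. The squared-deviation objective
#' \deqn{\sum_j (d_{i_j} - j T / k)^2}
#' is minimised exactly by dynamic programming over (candidate, slot) states,
#' so the selection is provably optimal, with ties broken towards lower
#' indices. The anchor (distance 0) is prepended to the returned selection.
#'
#' @param d_from_anchor nonnegative numeric vector of candidate distances, in
#'   path order.
#' @param k number of candidates to select (default 9, for a ten-image
#'   continuum including the anchor).
#' @param ids optional candidate labels (same length as `d_from_anchor`).
#' @param anchor_id label for the prepended anchor.
#' @param jump_factor passed to [detect_jumps()] for the screening flags.
#' @return a `"continuum_selection"`: `selected_ids` (anchor first),
#'   `selected_idx` (candidate indices, 1-based, excluding the anchor),
#'   `distances_from_anchor` (length `k + 1`, starting at 0, non-decreasing),
#'   `objective_value`, `jump_flags`.
#' @export
select_continuum <- function(d_from_anchor, k = 9, ids = NULL,
                             anchor_id = "anchor", jump_factor = 2.0) {
  d <- as.numeric(d_from_anchor)
  m <- length(d)
  if (!all(is.finite(d)) || any(d < 0)) stop("distances must be finite and nonnegative")
  if (k < 1 || k != as.integer(k)) stop("`k` must be a positive integer")
  if (m < k) stop(sprintf("need at least k = %d candidates, got %d", k, m))
  ids <- ids %||% sprintf("step%03d", seq_len(m))
  Tspan <- max(d)
  target <- seq_len(k) * Tspan / k

  # DP over slots j = 1..k and candidates i; cost[j, i] = best objective of
  # placing slot j at candidate i with a feasible monotone prefix.
  cost <- matrix(Inf, k, m)
  ptr <- matrix(NA_integer_, k, m)
  cost[1, ] <- (d - target[1])^2
  if (k > 1) {
    for (j in 2:k) {
      for (i in j:m) {
        prev <- seq_len(i - 1)
        ok <- prev[d[prev] <= d[i] & is.finite(cost[j - 1, prev])]
        if (length(ok)) {
          best <- ok[which.min(cost[j - 1, ok])]
          cost[j, i] <- cost[j - 1, best] + (d[i] - target[j])^2
          ptr[j, i] <- best
        }
      }
    }
  }
  if (!any(is.finite(cost[k, ]))) {
    # report the longest non-decreasing subsequence so the caller can see
    # where the path's monotone structure is insufficient
    lnds <- rep(1L, m)
    for (i in seq_len(m)) {
      prev <- which(d[seq_len(i - 1)] <= d[i])
      if (length(prev)) lnds[i] <- 1L + max(lnds[prev])
    }
    stop(sprintf(paste0(
      "fewer than k = %d candidates admit a monotone (non-decreasing) ",
      "selection: longest non-decreasing subsequence has length %d; ",
      "distances peak at candidate %d"), k, max(lnds), which.max(d)))
  }
  end <- which.min(cost[k, ])
  sel <- integer(k)
  sel[k] <- end
  if (k > 1) for (j in k:2) sel[j - 1] <- ptr[j, sel[j]]
  dist_sel <- c(0, d[sel])
  structure(
    list(selected_ids = c(anchor_id, ids[sel]),
         selected_idx = sel,
         distances_from_anchor = dist_sel,
         objective_value = cost[k, end],
         jump_flags = jump_increments(dist_sel, jump_factor)),
    class = "continuum_selection"
  )
}

#' @export
print.continuum_selection <- function(x, ...) {
  cat(sprintf("Continuum of %d images (anchor + %d), objective %.4g\n",
              length(x$selected_ids), length(x$selected_idx), x$objective_value))
  cat("distances:", paste(format(round(x$distances_from_anchor, 4)), collapse = " "), "\n")
  if (any(x$jump_flags)) {
    cat("perceptual jumps flagged at consecutive pairs:",
        paste(which(x$jump_flags), collapse = ", "), "\n")
  }
  invisible(x)
}

jump_increments <- function(distances, factor) {
  inc <- diff(distances)
  if (length(inc) < 2L) return(rep(FALSE, length(inc)))
  med <- stats::median(inc)
  if (!is.finite(med) || med <= 0) return(rep(FALSE, length(inc)))
  inc > factor * med
}

#' Screen a continuum for perceptual jumps
#'
#' Flags consecutive image pairs whose distance increment exceeds
#' `factor` times the median increment — the signature of an abrupt
#' perceptual transition along an otherwise smooth continuum.
#'
#' @param selection a `"continuum_selection"` or a numeric vector of
#'   cumulative distances from the anchor (>= 3 values).
#' @param factor multiplier on the median increment (default 2).
#' @return logical vector, one flag per consecutive pair.
#' @export
detect_jumps <- function(selection, factor = 2.0) {
  distances <- if (inherits(selection, "continuum_selection")) {
    selection$distances_from_anchor
  } else {
    as.numeric(selection)
  }
  if (length(distances) < 3L) stop("need at least 3 selected images")
  assert_scalar_number(factor, "factor", lower = 0)
  jump_increments(distances, factor)
}
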