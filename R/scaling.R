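#' One-dimensional perceptual embedding scale
#'
#' Container for a fitted perceptual scale. Scales are normalized to span
#' `[0, 1]` and oriented so that the anchor image (index 1) sits at the low
#' end; a fitted 1-D embedding is only identified up to an affine map and a
#' reflection, and this convention pins both down.
#'
#' @param psi numeric vector of scale values (dim 1) or an `n x d` matrix
#'   for higher-dimensional embeddings (left unnormalized).
#' @param method one of `"mlds"`, `"soe"`, `"tste"`.
#' @param sigma_hat MLDS noise estimate on the normalized scale (`NA` for
#'   the ordinal embeddings).
#' @param loss final objective value (negative log-likelihood or hinge loss).
#' @param converged logical optimizer status.
#' @param object_id optional object-set label.
#' @param seed seed used for the stochastic restarts.
#' @return an `"embedding_scale"` list with fields `psi_hat`, `method`,
#'   `sigma_hat`, `loss`, `converged`, `object_id`, `seed`.
#' @export
embedding_scale <- function(psi, method = c("mlds", "soe", "tste"),
                            sigma_hat = NA_real_, loss = NA_real_,
                            converged = NA, object_id = NULL, seed = NULL) {
  method <- match.arg(method)
  es <- structure(
    list(psi_hat = psi, method = method, sigma_hat = sigma_hat,
         loss = loss, converged = converged, object_id = object_id,
         seed = seed),
    class = "embedding_scale"
  )
  if (is.null(dim(psi))) normalize_embedding(es) else es
}

#' Normalize an embedding scale to [0, 1] with the anchor at the low end
#'
#' Min–max normalizes a 1-D scale and reflects it if the anchor (index 1)
#' falls in the upper half, so the anchor maps to 0 whenever it is an
#' extreme point. The MLDS noise estimate is rescaled by the same factor so
#' `sigma_hat` stays interpretable on the normalized scale. The operation is
#' idempotent.
#'
#' @param es an `"embedding_scale"` (1-D) or a numeric vector.
#' @return the normalized object (same type as the input).
#' @export
normalize_embedding <- function(es) {
  if (is.numeric(es) && is.null(dim(es))) {
    return(normalize_psi(es)$psi)
  }
  stopifnot(inherits(es, "embedding_scale"))
  if (!is.null(dim(es$psi_hat))) return(es)  # multi-dim configurations kept as-is
  nz <- normalize_psi(es$psi_hat)
  es$psi_hat <- nz$psi
  if (!is.na(es$sigma_hat)) es$sigma_hat <- es$sigma_hat / nz$scale
  es
}

normalize_psi <- function(psi) {
  rng <- range(psi)
  span <- rng[2] - rng[1]
  if (span <= 0) stop("degenerate scale: all psi values equal")
  p <- (psi - rng[1]) / span
  if (p[1] > 0.5) p <- 1 - p
  list(psi = p, scale = span)
}

#' @export
print.embedding_scale <- function(x, ...) {
  cat(sprintf("Perceptual scale (%s)%s: n = %d, loss = %.4g, converged = %s\n",
              x$method,
              if (is.null(x$object_id)) "" else paste0(" [", x$object_id, "]"),
              NROW(x$psi_hat), x$loss, x$converged))
  if (is.null(dim(x$psi_hat))) {
    cat("psi:", paste(format(round(x$psi_hat, 3)), collapse = " "), "\n")
  }
  if (!is.na(x$sigma_hat)) cat(sprintf("sigma_hat = %.4g\n", x$sigma_hat))
  invisible(x)
}

# ---- shared response preparation -------------------------------------------

prepare_responses <- function(responses, n = NULL, require_all = TRUE) {
  df <- as.data.frame(responses)
  needed <- c("reference", "probe_left", "probe_right", "choice")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) stop("responses missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("empty response set")
  idx <- c(df$reference, df$probe_left, df$probe_right)
  if (anyNA(idx) || !is.numeric(idx)) stop("image indices must be complete and numeric")
  n <- n %||% max(idx)
  if (n < 3) stop("need at least 3 images")
  if (any(idx < 1 | idx > n)) stop("image index outside 1..n")
  if (require_all) {
    absent <- setdiff(seq_len(n), sort(unique(idx)))
    if (length(absent)) {
      stop("degenerate data: image(s) never judged: ",
           paste(absent, collapse = ", "))
    }
  }
  y <- df$choice == "left"
  list(ref = df$reference,
       chosen = ifelse(y, df$probe_left, df$probe_right),
       other = ifelse(y, df$probe_right, df$probe_left),
       left = df$probe_left, right = df$probe_right, y = y, n = n)
}

# ---- MLDS -------------------------------------------------------------------

#' Maximum likelihood difference scaling for triads
#'
#' Fits a 1-D perceptual scale `psi` and noise SD `sigma` to triplet
#' judgements by maximizing
#' \deqn{\sum \log \Phi\big(\pm(|\psi_i - \psi_k| - |\psi_i - \psi_j|)/
#'       (\sigma\sqrt 2)\big),}
#' the triad adaptation of classic difference scaling: the decision variable
#' is the difference of the two unsigned scale distances from the reference.
#' The scale is anchored with `psi[1] = 0`, `psi[n] = 1` during optimization
#' and the interior values constrained to `[0, 1]`; the returned scale is
#' re-normalized (see [normalize_embedding()]). Optimization uses L-BFGS-B
#' with `n_restarts` random restarts (the first start is the equispaced
#' scale), keeping the best solution.
#'
#' @param responses response table with columns `reference`, `probe_left`,
#'   `probe_right`, `choice`.
#' @param n number of images (default: largest index present).
#' @param n_restarts random restarts (>= 1; default 5).
#' @param seed seed for the restarts.
#' @param maxit optimizer iteration cap.
#' @param object_id carried into the result.
#' @return an `"embedding_scale"` with `method = "mlds"` and `sigma_hat`.
#' @export
fit_mlds <- function(responses, n = NULL, n_restarts = 5, seed = NULL,
                     maxit = 500, object_id = NULL) {
  pr <- prepare_responses(responses, n)
  n <- pr$n
  set_seed_if(seed)

  nll <- function(par) {
    psi <- c(0, par[seq_len(n - 2)], 1)
    sigma <- exp(par[n - 1])
    z <- (abs(psi[pr$ref] - psi[pr$other]) -
            abs(psi[pr$ref] - psi[pr$chosen])) / (sigma * sqrt(2))
    -sum(stats::pnorm(z, log.p = TRUE))
  }

  inits <- vector("list", max(1, n_restarts))
  inits[[1]] <- c(seq_len(n - 2) / (n - 1), log(0.2))
  for (r in seq_along(inits)[-1]) {
    inits[[r]] <- c(sort(stats::runif(n - 2)), log(stats::runif(1, 0.05, 0.5)))
  }
  lower <- c(rep(0, n - 2), log(1e-4))
  upper <- c(rep(1, n - 2), log(10))

  best <- NULL
  for (init in inits) {
    fit <- try(stats::optim(init, nll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = maxit, factr = 1e2)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("MLDS optimization failed: non-finite likelihood")
  }
  psi <- c(0, best$par[seq_len(n - 2)], 1)
  embedding_scale(psi, "mlds",
                  sigma_hat = exp(best$par[n - 1]),
                  loss = best$value,
                  converged = best$convergence == 0,
                  object_id = object_id, seed = seed)
}

#' Log-likelihood of triplet responses under a fixed MLDS scale
#'
#' Evaluates the triad difference-scaling log-likelihood at given `psi` and
#' `sigma` without fitting — useful for closed-form checks and model
#' comparison.
#'
#' @inheritParams fit_mlds
#' @param psi scale values.
#' @param sigma noise SD (> 0).
#' @export
mlds_loglik <- function(responses, psi, sigma) {
  pr <- prepare_responses(responses, length(psi), require_all = FALSE)
  z <- (abs(psi[pr$ref] - psi[pr$other]) -
          abs(psi[pr$ref] - psi[pr$chosen])) / (sigma * sqrt(2))
  sum(stats::pnorm(z, log.p = TRUE))
}

# ---- ordinal embeddings -----------------------------------------------------

embed_distances <- function(X, a, b) {
  if (is.null(dim(X))) return(abs(X[a] - X[b]))
  sqrt(rowSums((X[a, , drop = FALSE] - X[b, , drop = FALSE])^2))
}

# Quasi-Newton fit of a point configuration: several random restarts at
# mixed initialization scales, then a long polishing run on the most
# promising candidates. Candidates are screened both by loss and by
# training triplet error — an expanded but mis-ordered configuration can
# transiently beat a correct one on the smooth losses, so the error-based
# candidate guards against committing to the wrong basin.
fit_embedding <- function(pr, dim, loss_fn, method, n_restarts, seed, maxit,
                          object_id) {
  n <- pr$n
  set_seed_if(seed)
  obj <- function(par) loss_fn(matrix(par, n, dim))
  train_err <- function(par) {
    X <- matrix(par, n, dim)
    dc <- embed_distances(X, pr$ref, pr$chosen)
    do_ <- embed_distances(X, pr$ref, pr$other)
    mean(ifelse(dc == do_, 0.5, as.numeric(dc > do_)))
  }
  init_sds <- rep(c(0.1, 0.3, 1), length.out = max(1, n_restarts))
  cands <- list()
  for (r in seq_len(max(1, n_restarts))) {
    init <- stats::rnorm(n * dim, sd = init_sds[r])
    fit <- try(stats::optim(init, obj, method = "BFGS",
                            control = list(maxit = maxit, reltol = 1e-10)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$value)) {
      cands[[length(cands) + 1L]] <- fit
    }
  }
  if (!length(cands)) stop(method, " optimization failed: non-finite loss")
  losses <- vapply(cands, `[[`, numeric(1), "value")
  errs <- vapply(cands, function(f) train_err(f$par), numeric(1))
  best <- NULL
  for (i in unique(c(which.min(losses), which.min(errs)))) {
    fit <- try(stats::optim(cands[[i]]$par, obj, method = "BFGS",
                            control = list(maxit = 3 * maxit, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop(method, " optimization failed: non-finite loss")
  X <- matrix(best$par, n, dim)
  psi <- if (dim == 1L) drop(X) else X
  embedding_scale(psi, method, loss = best$value,
                  converged = best$convergence == 0,
                  object_id = object_id, seed = seed)
}

#' Soft ordinal embedding (SOE) from triplet responses
#'
#' Places the `n` images in `dim`-dimensional Euclidean space to satisfy the
#' judged triplets with a squared hinge loss:
#' \deqn{\sum \max(0,\; d(r, chosen) + margin - d(r, other))^2.}
#' Multiple random initializations are tried and the best configuration
#' kept. For `dim = 1` the configuration is returned as a normalized
#' [embedding_scale()].
#'
#' @inheritParams fit_mlds
#' @param dim embedding dimension (default 1).
#' @param margin hinge margin on the embedding scale (default 0.1).
#' @return an `"embedding_scale"` with `method = "soe"`.
#' @export
fit_soe <- function(responses, n = NULL, dim = 1, margin = 0.1,
                    n_restarts = 5, seed = NULL, maxit = 1000,
                    object_id = NULL) {
  pr <- prepare_responses(responses, n)
  loss <- function(X) {
    h <- pmax(0, embed_distances(X, pr$ref, pr$chosen) + margin -
                embed_distances(X, pr$ref, pr$other))
    sum(h^2)
  }
  fit_embedding(pr, as.integer(dim), loss, "soe", n_restarts, seed, maxit,
                object_id)
}

#' t-distributed stochastic triplet embedding (t-STE)
#'
#' Maximizes the triplet likelihood under a Student-t kernel,
#' \deqn{p = w_{chosen} / (w_{chosen} + w_{other}), \quad
#'       w(x) = (1 + d(r, x)^2/\alpha)^{-(\alpha+1)/2}.}
#' The heavy-tailed kernel keeps gradients informative for far-apart items.
#' The common `alpha = dim - 1` rule degenerates at `dim = 1`, so the
#' default here is `alpha = dim + 1` (2 in one dimension): in our
#' simulations very heavy tails (`alpha = 1`) visibly distort the recovered
#' spacing on fully consistent data, while `alpha = dim + 1` preserves it.
#' Pass `alpha` explicitly to override.
#'
#' @inheritParams fit_soe
#' @param alpha degrees of freedom of the Student-t kernel (> 0); default
#'   `dim + 1`.
#' @return an `"embedding_scale"` with `method = "tste"` whose `loss` is the
#'   negative log-likelihood.
#' @export
fit_tste <- function(responses, n = NULL, dim = 1, alpha = dim + 1,
                     n_restarts = 5, seed = NULL, maxit = 1000,
                     object_id = NULL) {
  pr <- prepare_responses(responses, n)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0) stop("`alpha` must be > 0")
  loss <- function(X) {
    lc <- tste_log_kernel(embed_distances(X, pr$ref, pr$chosen), alpha)
    lo <- tste_log_kernel(embed_distances(X, pr$ref, pr$other), alpha)
    sum(log1p(exp(lo - lc)))  # -sum log p, numerically stable
  }
  fit_embedding(pr, as.integer(dim), loss, "tste", n_restarts, seed, maxit,
                object_id)
}

tste_log_kernel <- function(d, alpha) {
  -(alpha + 1) / 2 * log1p(d^2 / alpha)
}

#' Negative log-likelihood of a t-STE configuration
#'
#' Direct evaluation of the t-STE objective at a fixed configuration.
#'
#' @inheritParams fit_tste
#' @param X numeric vector (1-D) or `n x d` matrix of positions.
#' @export
tste_loss <- function(responses, X, alpha = 1, n = NULL) {
  pr <- prepare_responses(responses, n %||% NROW(X), require_all = FALSE)
  lc <- tste_log_kernel(embed_distances(X, pr$ref, pr$chosen), alpha)
  lo <- tste_log_kernel(embed_distances(X, pr$ref, pr$other), alpha)
  sum(log1p(exp(lo - lc)))
}

# ---- triplet error and cross-validation ------------------------------------

#' Triplet error of an embedding on judged responses
#'
#' Fraction of responses whose chosen probe is *not* the nearer probe under
#' the embedding; exact distance ties count 0.5. This is the empirical
#' disagreement between the embedding's geometry and the judgements.
#'
#' @param embedding an `"embedding_scale"`, a numeric scale vector, or an
#'   `n x d` position matrix.
#' @param responses response table (see [fit_mlds()]).
#' @return a number in `[0, 1]`.
#' @export
triplet_error <- function(embedding, responses) {
  X <- if (inherits(embedding, "embedding_scale")) embedding$psi_hat else embedding
  pr <- prepare_responses(responses, NROW(X), require_all = FALSE)
  dc <- embed_distances(X, pr$ref, pr$chosen)
  do_ <- embed_distances(X, pr$ref, pr$other)
  mean(ifelse(dc == do_, 0.5, as.numeric(dc > do_)))
}

#' Cross-validated triplet error
#'
#' Splits the responses into `k` folds (seeded shuffle), fits the requested
#' scaling method on each training set and scores [triplet_error()] on the
#' held-out fold. The mean over folds is the cross-validated triplet error
#' of the method on this data set.
#'
#' @param responses response table.
#' @param method `"mlds"`, `"soe"` or `"tste"`.
#' @param k number of folds (default 10).
#' @param seed seed controlling the fold assignment and the fitters'
#'   restarts.
#' @param n number of images (default inferred).
#' @param ... passed to the fitter (e.g. `n_restarts`, `margin`, `alpha`).
#' @return a `"cv_result"` list: `fold_errors`, `mean_error`, `k`, `seed`,
#'   `fold_id` (test-fold index of every response).
#' @export
cross_validated_error <- function(responses, method = c("mlds", "soe", "tste"),
                                  k = 10, seed = NULL, n = NULL, ...) {
  method <- match.arg(method)
  df <- as.data.frame(responses)
  if (nrow(df) < k) stop("need at least k responses")
  pr <- prepare_responses(df, n)
  n <- pr$n
  set_seed_if(seed)
  fold_id <- sample(rep(seq_len(k), length.out = nrow(df)))
  fitter <- switch(method, mlds = fit_mlds, soe = fit_soe, tste = fit_tste)
  fold_errors <- vapply(seq_len(k), function(f) {
    train <- df[fold_id != f, , drop = FALSE]
    test <- df[fold_id == f, , drop = FALSE]
    idx <- c(train$reference, train$probe_left, train$probe_right)
    if (length(setdiff(seq_len(n), unique(idx)))) {
      stop(sprintf(paste0("training fold %d is missing image(s) %s; ",
                          "use a smaller k or more responses"),
                   f, paste(setdiff(seq_len(n), unique(idx)), collapse = ", ")))
    }
    es <- fitter(train, n = n, ...)
    triplet_error(es, test)
  }, numeric(1))
  structure(
    list(fold_errors = fold_errors, mean_error = mean(fold_errors),
         k = k, seed = seed, fold_id = fold_id),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV triplet error: mean %.4f (folds %s)\n",
              x$k, x$mean_error,
              paste(format(round(x$fold_errors, 3)), collapse = " ")))
  invisible(x)
}

#' Image order implied by a 1-D embedding
#'
#' @param embedding an `"embedding_scale"` or numeric scale vector.
#' @return integer permutation: image indices from the anchor end outward.
#' @export
embedding_order <- function(embedding) {
  psi <- if (inherits(embedding, "embedding_scale")) embedding$psi_hat else embedding
  if (!is.null(dim(psi))) stop("ordering requires a 1-D embedding")
  order(psi)
}

#' Rank agreement between two orderings across object sets
#'
#' Compares, object by object, the image order implied by one metric (e.g.
#' the model-based perceptual distance) with the order implied by another
#' (e.g. the human-derived embedding). Every image contributes a
#' `(rank under A, rank under B)` pair; the pooled Spearman correlation and
#' the `n x n` rank co-occurrence (confusion) matrix summarize the
#' agreement. Counts concentrated on the diagonal indicate that images tend
#' to occupy the same rank under both metrics.
#'
#' @param order_a,order_b lists (one element per object set) of integer
#'   permutations giving image indices in rank order; plain vectors are
#'   treated as single-object lists.
#' @return a `"rank_agreement"` list: `spearman_rho`, `confusion`
#'   (`n x n` integer matrix, rows = rank under A, cols = rank under B),
#'   `n_objects`.
#' @export
rank_agreement <- function(order_a, order_b) {
  if (!is.list(order_a)) order_a <- list(order_a)
  if (!is.list(order_b)) order_b <- list(order_b)
  if (length(order_a) != length(order_b)) stop("order lists must have equal length")
  n <- length(order_a[[1]])
  ra <- rb <- integer(0)
  for (i in seq_along(order_a)) {
    oa <- order_a[[i]]; ob <- order_b[[i]]
    if (length(oa) != n || length(ob) != n) stop("length mismatch at object ", i)
    if (!setequal(oa, seq_len(n)) || !setequal(ob, seq_len(n))) {
      stop("orders must be permutations of 1..n (object ", i, ")")
    }
    ra <- c(ra, match(seq_len(n), oa))  # rank of image j under A
    rb <- c(rb, match(seq_len(n), ob))
  }
  confusion <- table(factor(ra, levels = seq_len(n)),
                     factor(rb, levels = seq_len(n)))
  confusion <- matrix(as.integer(confusion), n, n,
                      dimnames = list(rank_a = seq_len(n), rank_b = seq_len(n)))
  structure(
    list(spearman_rho = stats::cor(ra, rb, method = "spearman"),
         confusion = confusion, n_objects = length(order_a)),
    class = "rank_agreement"
  )
}

#' @export
print.rank_agreement <- function(x, ...) {
  cat(sprintf("Rank agreement over %d object set(s): Spearman rho = %.3f\n",
              x$n_objects, x$spearman_rho))
  invisible(x)
}
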