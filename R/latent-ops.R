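#' Spherical linear interpolation between two latent vectors
#'
#' Interpolates along the great circle between two noise latents `u` and `v`.
#' Uniform steps in `t` correspond to uniform angular steps, so perceptual
#' continua built from slerp traverse the latent hypersphere at constant
#' angular speed. Vectors need not be unit norm; when the angle between them
#' falls below `tol` the great circle is numerically ill-conditioned and the
#' function falls back to linear interpolation with the norm interpolated
#' linearly between `||u||` and `||v||`.
#'
#' @param u,v numeric vectors of equal dimension (>= 2) and nonzero norm.
#' @param t interpolation parameter in `[0, 1]`; `t = 0` returns `u`,
#'   `t = 1` returns `v`.
#' @param tol angular tolerance (radians). Angles below `tol` trigger the
#'   linear fallback; angles within `tol` of `pi` (antiparallel vectors) are
#'   an error because the great circle is not unique.
#' @return a numeric vector of the same dimension as `u`.
#' @examples
#' slerp(c(1, 0), c(0, 1), 0.5)  # (sqrt(2)/2, sqrt(2)/2)
#' @export
slerp <- function(u, v, t, tol = 1e-7) {
  if (!is.numeric(u) || !is.numeric(v)) stop("latents must be numeric vectors")
  if (length(u) != length(v)) {
    stop(sprintf("dimension mismatch: length(u) = %d, length(v) = %d",
                 length(u), length(v)))
  }
  if (length(u) < 2L) stop("latent dimension must be >= 2")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("latents must be finite")
  assert_scalar_number(t, "t", 0, 1)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm latent: slerp undefined")
  cos_theta <- sum(u * v) / (nu * nv)
  cos_theta <- min(1, max(-1, cos_theta))
  theta <- acos(cos_theta)
  if (theta > pi - tol) {
    stop("antiparallel latents: great circle undefined (angle within tolerance of pi)")
  }
  if (theta < tol) {
    # near-parallel: lerp direction, interpolate the norm linearly
    w <- (1 - t) * u + t * v
    wn <- sqrt(sum(w^2))
    target <- (1 - t) * nu + t * nv
    if (wn > 0) w <- w * (target / wn)
    return(w)
  }
  (sin((1 - t) * theta) * u + sin(t * theta) * v) / sin(theta)
}

#' Build an interpolation path of interior slerp steps
#'
#' Places `n_steps` latents strictly between the anchor and guide latents at
#' `t_k = k / (n_steps + 1)`, `k = 1..n_steps`. Endpoints are excluded so that
#' "anchor plus `n_steps` interpolations" counts the images the way a stimulus
#' continuum is assembled (the anchor is the origin, the interpolations extend
#' towards the guide).
#'
#' @param u,v anchor and guide latent vectors (see [slerp()]).
#' @param n_steps number of interior interpolation points (>= 1).
#' @param ids character vector of length 2 naming the endpoints.
#' @param tol passed to [slerp()].
#' @return an object of class `"interp_path"`: a list with `endpoint_ids`,
#'   `t` (strictly increasing interior positions) and `latents`
#'   (`n_steps` x d matrix, one latent per row).
#' @export
build_path <- function(u, v, n_steps, ids = c("anchor", "guide"), tol = 1e-7) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != as.integer(n_steps)) {
    stop("`n_steps` must be a single integer >= 1")
  }
  n_steps <- as.integer(n_steps)
  t <- seq_len(n_steps) / (n_steps + 1)
  lat <- t(vapply(t, function(tt) slerp(u, v, tt, tol = tol),
                  numeric(length(u))))
  rownames(lat) <- sprintf("%s_t%03d", ids[1], seq_len(n_steps))
  structure(
    list(endpoint_ids = as.character(ids), t = t, latents = lat),
    class = "interp_path"
  )
}

#' @export
print.interp_path <- function(x, ...) {
  cat(sprintf("Interpolation path: %s -> %s, %d interior steps (d = %d)\n",
              x$endpoint_ids[1], x$endpoint_ids[2],
              length(x$t), ncol(x$latents)))
  invisible(x)
}

#' Read and write latent matrices as CSV
#'
#' One latent per row; the first column `id` carries the latent label and the
#' remaining columns `v1..vd` the coordinates.
#'
#' @param latents numeric matrix with one latent per row (rownames used as
#'   ids when present).
#' @param path file path.
#' @return `read_latents` returns a numeric matrix with ids as rownames.
#' @export
write_latents <- function(latents, path) {
  latents <- as.matrix(latents)
  ids <- rownames(latents) %||% sprintf("latent%03d", seq_len(nrow(latents)))
  df <- data.frame(id = ids, latents, row.names = NULL, check.names = FALSE)
  colnames(df) <- c("id", sprintf("v%d", seq_len(ncol(latents))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (colnames(df)[1] != "id") stop("latent CSV must start with an `id` column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("latent coordinates must be numeric")
  rownames(m) <- as.character(df$id)
  m
}

#' Write interpolation-path metadata as JSON
#'
#' Stores endpoint ids and `t` positions; the latents themselves travel as a
#' CSV via [write_latents()].
#'
#' @param path_obj an `"interp_path"`.
#' @param file destination JSON file.
#' @export
write_path_meta <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "interp_path"))
  jsonlite::write_json(
    list(endpoint_ids = path_obj$endpoint_ids, t = path_obj$t),
    file, auto_unbox = FALSE, digits = NA
  )
  invisible(file)
}

#' @rdname write_path_meta
#' @export
read_path_meta <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(endpoint_ids = as.character(x$endpoint_ids), t = as.numeric(x$t))
}
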