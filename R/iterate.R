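#' Random initial intensity
#'
#' I.i.d. uniform voxel values in `[-1, 1]`, reproducible per seed.
#'
#' @param n_q,n_theta Grid dimensions (`n_phi = 2 * n_theta`).
#' @param q_max Radial cutoff.
#' @param seed Integer RNG seed.
#' @return A [spherical_intensity()].
#' @export
random_init <- function(n_q, n_theta, q_max, seed) {
  n_phi <- 2L * n_theta
  set.seed(seed)
  vals <- array(stats::runif(n_q * n_theta * n_phi, -1, 1),
                c(n_q, n_theta, n_phi))
  spherical_intensity(vals, q_max)
}

#' One error-reduction (ER) iteration
#'
#' Sequential application of the projection operators:
#' `I' = P_s(P_m(I))`.
#'
#' @param si Current [spherical_intensity()].
#' @param basis [eigendecompose_b()] result (the modulus constraint).
#' @param mask [build_support_mask()] result (the support constraint).
#' @return The updated intensity.
#' @export
er_step <- function(si, basis, mask) {
  support_project(modulus_project(si, basis), mask)
}

#' One hybrid input-output (HIO) iteration
#'
#' The modulus-constraint output is kept where the combined
#' support-and-positivity constraint is already satisfied there (i.e. where
#' `P_s(P_m(I))` equals `P_m(I)`); elsewhere the negative feedback
#' `I - beta * P_m(I)` is applied.
#'
#' @param si Current [spherical_intensity()].
#' @param basis Modulus constraint basis.
#' @param mask Support mask.
#' @param beta Feedback parameter in `(0, 2)`; 0.9 in typical use.
#' @return The updated intensity.
#' @export
hio_step <- function(si, basis, mask, beta = 0.9) {
  pm <- modulus_project(si, basis)
  ps <- support_project(pm, mask)
  good <- ps$values == pm$values
  si$values <- ifelse(good, pm$values, si$values - beta * pm$values)
  si
}

#' Parse an iterative-algorithm recipe string
#'
#' Grammar: comma-separated `<count><scheme>` tokens (scheme `ER` or `HIO`,
#' case-insensitive), optionally followed by a whitespace-separated `xK`
#' suffix repeating the whole sequence K times. Example: `"20HIO,2ER x5"`
#' parses to 110 iterations.
#'
#' @param recipe Recipe string.
#' @param beta HIO feedback parameter in `(0, 2)`.
#' @return A `recipe` object: data frame of `(scheme, count)` segments,
#'   `beta`, and the total iteration count `n_iter`.
#' @export
parse_recipe <- function(recipe, beta = 0.9) {
  if (beta <= 0 || beta >= 2)
    stop("beta must lie in (0, 2)", call. = FALSE)
  s <- trimws(recipe)
  reps <- 1L
  m <- regmatches(s, regexec("^(.*?)[[:space:]]*[xX]([0-9]+)$", s))[[1]]
  if (length(m) == 3) {
    s <- m[2]
    reps <- as.integer(m[3])
    if (reps < 1) stop("repeat count must be >= 1", call. = FALSE)
  }
  toks <- trimws(strsplit(s, ",")[[1]])
  if (!length(toks)) stop("empty recipe", call. = FALSE)
  seg <- lapply(toks, function(t) {
    mm <- regmatches(t, regexec("^([0-9]+)[[:space:]]*(ER|HIO)$", t,
                                ignore.case = TRUE))[[1]]
    if (length(mm) != 3)
      stop(sprintf("cannot parse recipe token '%s'", t), call. = FALSE)
    n <- as.integer(mm[2])
    if (n < 1) stop("iteration counts must be positive", call. = FALSE)
    data.frame(scheme = toupper(mm[3]), count = n)
  })
  seg <- do.call(rbind, seg)
  seg <- seg[rep(seq_len(nrow(seg)), reps), , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(segments = seg, beta = beta, n_iter = sum(seg$count)),
            class = "recipe")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("recipe: %s (beta=%.2f, %d iterations)\n",
              paste(sprintf("%d%s", x$segments$count, x$segments$scheme),
                    collapse = ","),
              x$beta, x$n_iter))
  invisible(x)
}

#' Run an iterative recovery recipe
#'
#' Executes the recipe's ER/HIO segments in order, starting from `init`.
#' When a reference peak list is supplied, the crystallographic R factor
#' between the reference intensities and the intensities extracted from the
#' support-projected iterate is recorded at every iteration.
#'
#' @param init Initial [spherical_intensity()] (e.g. [random_init()]).
#' @param recipe A [parse_recipe()] object or recipe string.
#' @param basis [eigendecompose_b()] result.
#' @param mask [build_support_mask()] result.
#' @param reference Optional [bragg_peaks()] list with target intensities.
#' @return A `run_state`: final intensity `intensity`, per-iteration scheme
#'   labels, the R-factor `trace` (NA-free only with a reference), and the
#'   extracted final intensities when a reference was given.
#' @export
run_recipe <- function(init, recipe, basis, mask, reference = NULL) {
  if (is.character(recipe)) recipe <- parse_recipe(recipe)
  stopifnot(inherits(recipe, "recipe"))
  si <- init
  trace <- numeric(0)
  schemes <- character(0)
  for (g in seq_len(nrow(recipe$segments))) {
    scheme <- recipe$segments$scheme[g]
    for (it in seq_len(recipe$segments$count[g])) {
      si <- if (scheme == "ER") er_step(si, basis, mask)
            else hio_step(si, basis, mask, recipe$beta)
      schemes <- c(schemes, scheme)
      if (!is.null(reference)) {
        rec <- extract_peak_intensities(support_project(si, mask), mask)
        trace <- c(trace, r_factor(rec$intensity, reference$intensity))
      } else trace <- c(trace, NA_real_)
    }
  }
  out <- list(intensity = si, trace = trace, schemes = schemes,
              n_iter = recipe$n_iter)
  if (!is.null(reference)) {
    final <- support_project(si, mask)
    out$recovered <- extract_peak_intensities(final, mask)
    out$final_r <- utils::tail(trace, 1)
  }
  structure(out, class = "run_state")
}

#' @export
print.run_state <- function(x, ...) {
  cat(sprintf("run state: %d iterations", x$n_iter))
  if (!is.null(x$final_r)) cat(sprintf(", final R = %.4f", x$final_r))
  cat("\n")
  invisible(x)
}
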