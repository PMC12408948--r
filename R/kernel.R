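#' Discretization mesh over the length domain
#'
#' The length domain Omega is cut into `n_bins` equal-width bins; all kernel
#' functions are evaluated at the bin midpoints (midpoint rule). The default
#' bounds cover the offspring size distribution (4 sd below the birth length)
#' and growth overshoot above the asymptotic maximum (4 sd of the growth
#' spread above `L_m`).
#'
#' @param params a [deb_params()] object.
#' @param n_bins number of bins (default 200).
#' @param cv_g coefficient of variation of the growth kernel.
#' @param cv_b coefficient of variation of the offspring-size kernel.
#' @param lower,upper optional explicit domain bounds (cm).
#' @return An object of class `"length_mesh"`: list with `n_bins`, `lower`,
#'   `upper`, `midpoints`, `width`, `edges`.
#' @export
length_mesh <- function(params, n_bins = 200, cv_g = 0.1, cv_b = 0.1,
                        lower = NULL, upper = NULL) {
  if (is.null(lower)) lower <- max(1e-3, params$L_b * (1 - 4 * cv_b))
  if (is.null(upper)) upper <- params$L_m * (1 + 4 * cv_g)
  if (!(lower > 0 && upper > lower)) stop("invalid mesh bounds")
  edges <- seq(lower, upper, length.out = n_bins + 1)
  width <- (upper - lower) / n_bins
  mesh <- list(n_bins = as.integer(n_bins), lower = lower, upper = upper,
               midpoints = (edges[-1] + edges[-(n_bins + 1)]) / 2,
               width = width, edges = edges)
  class(mesh) <- "length_mesh"
  mesh
}

#' Starvation threshold length
#'
#' Individuals die of starvation when their length exceeds
#' `L_m * E(Y) / kappa`. At `E(Y) = kappa` the threshold equals the maximum
#' length `L_m`, so starvation strikes exactly at the asymptote.
#'
#' @param params a [deb_params()] object.
#' @param EY experienced feeding level in \[0, 1\].
#' @return Threshold length (cm).
#' @export
starvation_threshold <- function(params, EY) {
  check_feeding_level(EY)
  params$L_m * EY / params$kappa
}

#' Annual survival probability at length L
#'
#' Survival over one year is `exp(-mu_j)` for juveniles (`L < L_p`) and
#' `exp(-mu_a)` for adults, and drops to zero above the starvation
#' threshold. A length exactly at `L_p` counts as adult.
#'
#' @param L length (cm); vectorized.
#' @inheritParams starvation_threshold
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_prob <- function(L, params, EY) {
  thr <- starvation_threshold(params, EY)
  s <- ifelse(L < params$L_p, exp(-params$mu_j), exp(-params$mu_a))
  s[L > thr] <- 0
  s
}

#' Expected length after one year of von Bertalanffy growth
#'
#' `L + (E(Y) * L_m - L) * (1 - exp(-r_B))`: growth towards the
#' feeding-level-dependent asymptote `E(Y) * L_m`. Individuals above the
#' asymptote shrink (the expected length falls below `L`).
#'
#' @inheritParams survival_prob
#' @return Expected length one year later (cm); vectorized in `L`.
#' @export
growth_mean <- function(L, params, EY) {
  check_feeding_level(EY)
  L + (EY * params$L_m - L) * (1 - exp(-params$r_B))
}

#' Gaussian growth kernel density
#'
#' Density of next year's length given current length `L`: normal with mean
#' [growth_mean()] and standard deviation `cv_g` times that mean.
#'
#' @param L_next candidate length next year (cm); vectorized.
#' @inheritParams survival_prob
#' @param cv_g coefficient of variation of the growth spread (> 0).
#' @export
growth_kernel_density <- function(L_next, L, params, EY, cv_g = 0.1) {
  if (cv_g <= 0) stop("cv_g must be > 0")
  m <- growth_mean(L, params, EY)
  if (any(m <= 0)) stop("degenerate parameters: expected length <= 0")
  stats::dnorm(L_next, mean = m, sd = cv_g * m)
}

#' Annual reproduction rate at length L
#'
#' Adults (`L >= L_p`) produce offspring at rate `R_m * E(Y) * L^2 / L_m^2`
#' (surface-area scaling of the Kooijman-Metz model); juveniles do not
#' reproduce. The rate equals `R_m` at `L = L_m` under `E(Y) = 1`.
#'
#' @inheritParams survival_prob
#' @return Offspring per year; vectorized in `L`.
#' @export
reproduction_rate <- function(L, params, EY) {
  check_feeding_level(EY)
  ifelse(L < params$L_p, 0,
         params$R_m * EY * L^2 / params$L_m^2)
}

#' Offspring-size kernel density
#'
#' Offspring lengths are normal around the birth length `L_b` with standard
#' deviation `cv_b * L_b`, independent of parent length.
#'
#' @param L_next offspring length (cm); vectorized.
#' @param params a [deb_params()] object.
#' @param cv_b coefficient of variation of offspring size (> 0).
#' @export
offspring_density <- function(L_next, params, cv_b = 0.1) {
  if (cv_b <= 0) stop("cv_b must be > 0")
  stats::dnorm(L_next, mean = params$L_b, sd = cv_b * params$L_b)
}

#' Discretize the projection kernel for one species and feeding level
#'
#' Builds the component matrices on the mesh midpoints: diagonal survival
#' `S`, column-stochastic growth `G`, diagonal reproduction `R`, the
#' offspring-size matrix `D`, recruitment `V = D R`, survival-growth
#' transition `U = G S`, and the full annual projection matrix
#' `A = (D R + G) S = V S + U`. Columns of `G` and `D` are renormalized to
#' unit mass within the domain so that no probability is lost by eviction
#' at the mesh edges.
#'
#' @inheritParams starvation_threshold
#' @param mesh a [length_mesh()]; built from `params` if `NULL`.
#' @param cv_g,cv_b kernel coefficients of variation.
#' @return Object of class `"deb_kernel"`: list with matrices `S`, `G`, `R`,
#'   `D`, `V`, `U`, `A`, the `mesh`, `params`, `EY`, and a logical
#'   `nonviable` flag (`TRUE` when `A` is identically zero).
#' @export
build_kernel <- function(params, EY, mesh = NULL, cv_g = 0.1, cv_b = 0.1) {
  check_feeding_level(EY)
  if (is.null(mesh)) mesh <- length_mesh(params, cv_g = cv_g, cv_b = cv_b)
  mid <- mesh$midpoints
  n <- mesh$n_bins

  if (params$L_b - 4 * cv_b * params$L_b < mesh$lower - 1e-9 ||
      params$L_b + 4 * cv_b * params$L_b > mesh$upper + 1e-9)
    warning("mesh does not cover the offspring size distribution (L_b +/- 4 sd)")

  s <- survival_prob(mid, params, EY)
  S <- diag(s, n)

  gm <- growth_mean(mid, params, EY)
  if (any(gm <= 0)) stop("degenerate parameters: expected length <= 0 on mesh")
  # G[i, j]: from bin j (column) to bin i (row), midpoint rule then
  # column renormalization (anti-eviction)
  G <- outer(mid, seq_len(n),
             function(x, j) stats::dnorm(x, mean = gm[j], sd = cv_g * gm[j])) *
    mesh$width
  G <- sweep(G, 2, colSums(G), "/")

  R <- diag(reproduction_rate(mid, params, EY), n)

  d <- offspring_density(mid, params, cv_b) * mesh$width
  d <- d / sum(d)
  D <- matrix(d, nrow = n, ncol = n)

  V <- D %*% R
  U <- G %*% S
  A <- V %*% S + U

  out <- list(S = S, G = G, R = R, D = D, V = V, U = U, A = A,
              mesh = mesh, params = params, EY = EY,
              cv_g = cv_g, cv_b = cv_b,
              nonviable = all(A == 0))
  class(out) <- "deb_kernel"
  out
}

#' @export
print.deb_kernel <- function(x, ...) {
  cat(sprintf("DEB-IPM kernel: %d x %d bins on [%.3g, %.3g] cm, E(Y) = %.2f\n",
              x$mesh$n_bins, x$mesh$n_bins, x$mesh$lower, x$mesh$upper, x$EY))
  if (x$nonviable) cat("  non-viable (projection matrix is zero)\n")
  invisible(x)
}
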