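#' Asymptotic growth rate, damping ratio and stable structure
#'
#' The population growth rate `lambda` is the spectral radius of the annual
#' projection matrix `A`; the damping ratio `xi = lambda / |lambda_2|`
#' (with `lambda_2` the highest subdominant eigenvalue) measures the speed
#' of convergence to the stable length distribution `w`, and is used as a
#' measure of demographic resilience.
#'
#' @param A square non-negative projection matrix, or a `"deb_kernel"`.
#' @return List with `lam`, `lam2_mod`, `xi`, and stable distribution `w`
#'   (sums to 1). For a dead population (`lambda = 0`) `xi` is `NA`; when
#'   `|lambda_2| = 0`, `xi` is `Inf`.
#' @export
population_metrics <- function(A) {
  if (inherits(A, "deb_kernel")) A <- A$A
  eg <- eigen(A)
  mods <- Mod(eg$values)
  k <- which.max(mods)
  lam <- mods[k]
  lam2 <- if (length(mods) > 1) max(mods[-k]) else 0
  w <- Re(eg$vectors[, k])
  if (sum(w) < 0) w <- -w
  sw <- sum(w)
  w <- if (sw != 0) w / sw else rep(NA_real_, length(w))
  xi <- if (lam == 0) NA_real_ else if (lam2 == 0) Inf else lam / lam2
  list(lam = lam, lam2_mod = lam2, xi = xi, w = w)
}

#' Fundamental and next-generation matrices
#'
#' `N = (I - U)^{-1}` (with `U = G S` the survival-growth transition) gives
#' the expected number of years spent in each length bin before death;
#' `F = (V S) N` is the next-generation matrix whose dominant eigenvalue is
#' the net reproductive rate `R0`. Recruitment enters the annual projection
#' `A = (V + G) S` as `V S` (survivors reproduce), so the same effective
#' recruitment is used here: that way `R0` crosses 1 exactly when `lambda`
#' does.
#'
#' @param kernel a `"deb_kernel"`, or a list with matrices `U` and `V`
#'   (and optionally `S`; identity assumed when absent).
#' @return List with `N` and `F`.
#' @export
fundamental_and_nextgen <- function(kernel) {
  U <- kernel$U
  V <- kernel$V
  if (!is.null(kernel$S)) V <- V %*% kernel$S
  rho_U <- max(Mod(eigen(U, only.values = TRUE)$values))
  if (rho_U >= 1)
    stop(sprintf(
      "spectral radius of survival-growth transition is %.6f >= 1 %s",
      rho_U,
      if (!is.null(kernel$params) && !is.na(kernel$params$species))
        paste0("(species ", kernel$params$species, ")") else ""))
  n <- nrow(U)
  N <- solve(diag(n) - U)
  list(N = N, F = V %*% N)
}

#' Net reproductive rate
#'
#' Dominant eigenvalue of the next-generation matrix `F`: the mean number
#' of recruits produced over an individual's lifetime.
#'
#' @param derived output of [fundamental_and_nextgen()], or a matrix `F`.
#' @export
net_reproductive_rate <- function(derived) {
  F <- if (is.list(derived)) derived$F else derived
  max(Mod(eigen(F, only.values = TRUE)$values))
}

#' Generation time
#'
#' `T = log(R0) / log(lambda)`: the number of years for the population to
#' be replaced. Undefined (returned as `NA`) when `lambda` is at the
#' replacement point (`|log lambda| < 1e-10`), where the ratio degenerates.
#'
#' @param lam population growth rate (> 0).
#' @param R0 net reproductive rate (> 0).
#' @export
generation_time <- function(lam, R0) {
  if (!is.finite(lam) || !is.finite(R0) || lam <= 0 || R0 <= 0)
    return(NA_real_)
  if (abs(log(lam)) < 1e-10) return(NA_real_)
  log(R0) / log(lam)
}

#' Life expectancy and its juvenile/adult decomposition
#'
#' The column of the fundamental matrix `N` for the bin containing the
#' birth length gives expected years spent in every bin before death. Its
#' total is the mean life expectancy `eta_e`; the juvenile part (bins with
#' midpoint below `L_p`) is the age at maturity `L_alpha` and the adult
#' part the mature life expectancy `L_omega`, so that
#' `eta_e = L_alpha + L_omega` holds exactly.
#'
#' @param N fundamental matrix.
#' @param mesh the [length_mesh()] the kernel was built on.
#' @param params a [deb_params()] object.
#' @return List with `eta_e`, `L_alpha`, `L_omega`.
#' @export
life_expectancy_decomposition <- function(N, mesh, params) {
  if (params$L_b < mesh$lower || params$L_b > mesh$upper)
    stop("birth length L_b lies outside the mesh")
  birth_bin <- findInterval(params$L_b, mesh$edges, rightmost.closed = TRUE)
  col <- N[, birth_bin]
  juv <- mesh$midpoints < params$L_p
  list(eta_e = sum(col), L_alpha = sum(col[juv]), L_omega = sum(col[!juv]))
}

#' Age-from-stage survivorship and fertility schedules
#'
#' Starting from the offspring-size distribution (a column of `D`),
#' `l_x` is the probability of surviving to age at least `x` (total mass of
#' `U^x` applied to the birth distribution) and `m_x` the average per-capita
#' recruit production of survivors of age `x` (the column sums of `V`
#' applied to the age-`x` distribution, divided by `l_x`). The schedule is
#' truncated at the first age with `l_x < tol` or at `x_max`.
#'
#' @param kernel a `"deb_kernel"`.
#' @param x_max hard cap on age (years).
#' @param tol truncation tolerance on survivorship.
#' @return List with vectors `x`, `l_x`, `m_x`.
#' @export
age_schedules <- function(kernel, x_max = 5000, tol = 1e-9) {
  b <- kernel$D[, 1]
  b <- b / sum(b)
  Veff <- if (!is.null(kernel$S)) kernel$V %*% kernel$S else kernel$V
  v <- colSums(Veff)
  U <- kernel$U
  lx <- numeric(x_max + 1)
  mx <- numeric(x_max + 1)
  n_age <- 0L
  vec <- b
  for (x in 0:x_max) {
    l <- sum(vec)
    if (x > 0 && l < tol) break
    lx[x + 1] <- l
    mx[x + 1] <- if (l > 0) sum(v * vec) / l else 0
    n_age <- x + 1L
    if (l == 0) break
    vec <- U %*% vec
  }
  list(x = 0:(n_age - 1L), l_x = lx[seq_len(n_age)], m_x = mx[seq_len(n_age)])
}

#' Degree of iteroparity
#'
#' Ratio of the mean to the standard deviation of the fertility schedule
#' `m_x` over ages 0..ceiling(`eta_e`) (population standard deviation,
#' divisor `n`). Large values indicate reproduction spread evenly across
#' ages; a constant schedule has zero spread and the ratio is `Inf`.
#'
#' @param schedule output of [age_schedules()].
#' @param eta_e mean life expectancy (years); sets the age range.
#' @export
iteroparity <- function(schedule, eta_e) {
  upto <- min(length(schedule$m_x), ceiling(eta_e) + 1)
  m <- schedule$m_x[seq_len(upto)]
  if (length(m) < 2) return(NA_real_)
  mu <- mean(m)
  sdev <- sqrt(mean((m - mu)^2))
  if (sdev == 0) return(Inf)
  mu / sdev
}

#' Stable-stage-weighted vital rates
#'
#' Progressive growth `gamma` is the probability mass of the growth matrix
#' `G` moving to strictly larger bins, retrogressive growth `rho` the mass
#' moving to strictly smaller bins, and mean recruitment success `phi` the
#' per-capita recruit production (column sums of `V`); each is averaged
#' over source bins weighted by the stable length distribution `w`.
#'
#' @param kernel a `"deb_kernel"` (or list with `G` and `V`).
#' @param w stable stage distribution (sums to 1).
#' @return List with `gamma`, `rho`, `phi`.
#' @export
weighted_vital_rates <- function(kernel, w) {
  G <- kernel$G
  V <- kernel$V
  n <- nrow(G)
  lower_mask <- row(G) > col(G)   # destination bin larger than source
  upper_mask <- row(G) < col(G)
  up <- colSums(G * lower_mask)
  down <- colSums(G * upper_mask)
  list(gamma = sum(w * up), rho = sum(w * down), phi = sum(w * colSums(V)))
}

#' All life-history traits for one species at one feeding level
#'
#' Builds the kernel and derives the eight traits — generation time `T`,
#' age at maturity `L_alpha`, progressive growth `gamma`, retrogressive
#' growth `rho`, mean recruitment success `phi`, degree of iteroparity
#' `S_itero`, net reproductive rate `R0`, mature life expectancy `L_omega`
#' — together with `lambda`, the damping ratio `xi` and the mean life
#' expectancy `eta_e`. A record is flagged non-persistent when the
#' population declines (`lambda < 1`) or maturation is unreachable
#' (`E(Y) * L_m <= L_p`); undefined quantities propagate as `NA` without
#' aborting batch runs.
#'
#' @inheritParams build_kernel
#' @param n_bins mesh resolution.
#' @return One-row data.frame.
#' @export
trait_vector <- function(params, EY, n_bins = 200, cv_g = 0.1, cv_b = 0.1) {
  mesh <- length_mesh(params, n_bins = n_bins, cv_g = cv_g, cv_b = cv_b)
  K <- build_kernel(params, EY, mesh = mesh, cv_g = cv_g, cv_b = cv_b)
  pm <- population_metrics(K)
  row <- data.frame(species = params$species, EY = EY,
                    lambda = pm$lam, xi = pm$xi,
                    T = NA_real_, L_alpha = NA_real_, gamma = NA_real_,
                    rho = NA_real_, phi = NA_real_, S_itero = NA_real_,
                    R0 = NA_real_, L_omega = NA_real_, eta_e = NA_real_,
                    persistent = FALSE, stringsAsFactors = FALSE)
  if (K$nonviable || pm$lam == 0) return(row)
  der <- tryCatch(fundamental_and_nextgen(K), error = function(e) NULL)
  if (is.null(der)) return(row)
  R0 <- net_reproductive_rate(der)
  led <- life_expectancy_decomposition(der$N, mesh, params)
  sched <- age_schedules(K)
  wvr <- weighted_vital_rates(K, pm$w)
  row$T <- generation_time(pm$lam, R0)
  row$L_alpha <- led$L_alpha
  row$gamma <- wvr$gamma
  row$rho <- wvr$rho
  row$phi <- wvr$phi
  row$S_itero <- iteroparity(sched, led$eta_e)
  row$R0 <- R0
  row$L_omega <- led$L_omega
  row$eta_e <- led$eta_e
  row$persistent <- pm$lam >= 1 && EY * params$L_m > params$L_p
  row
}

#' Trait table for a set of species across feeding levels
#'
#' Applies [trait_vector()] to every species x feeding level combination.
#'
#' @param species_table data.frame from [read_species_csv()] or
#'   [sample_deb_params()].
#' @param feeding_levels feeding levels to evaluate (default low 0.6 and
#'   high 0.9).
#' @inheritParams trait_vector
#' @return data.frame, one row per species x feeding level.
#' @export
trait_table <- function(species_table, feeding_levels = c(0.6, 0.9),
                        n_bins = 200, cv_g = 0.1, cv_b = 0.1) {
  params <- species_params_list(species_table)
  rows <- list()
  for (p in params)
    for (f in feeding_levels)
      rows[[length(rows) + 1L]] <- trait_vector(p, f, n_bins = n_bins,
                                                cv_g = cv_g, cv_b = cv_b)
  do.call(rbind, rows)
}
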