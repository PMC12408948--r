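# Shared fixtures: the documentation species, hand-built matrix oracles,
# and a tiny two-bin mesh for decomposition tests.

toy <- make_toy_fixture()

# two-bin mesh: midpoints 1 and 2, bin edges 0.5/1.5/2.5; with L_p = 2 the
# first bin is juvenile and the second adult
mesh2 <- structure(list(n_bins = 2L, lower = 0.5, upper = 2.5,
                        midpoints = c(1, 2), width = 1,
                        edges = c(0.5, 1.5, 2.5)),
                   class = "length_mesh")
params2 <- deb_params(L_b = 1, L_p = 2, L_m = 3, r_B = 0.3, R_m = 1,
                      mu_j = 0.2, mu_a = 0.1)

# Leslie-type kernel wrapped in the list layout the trait functions expect
leslie_kernel <- function(A, U, V, D = NULL) {
  n <- nrow(A)
  if (is.null(D)) D <- matrix(rep(c(1, rep(0, n - 1)), n), n, n)
  list(A = A, U = U, V = V, D = D,
       G = diag(n), S = diag(n))
}

# cache for the expensive synthetic sweeps shared across acceptance blocks
.acc_cache <- new.env(parent = emptyenv())

# per-kernel demographic bundle used by the identity and cross-validation
# suites: everything is recomputed from the kernel, not from trait_vector()
kernel_demography <- function(params, EY, n_bins = 200) {
  K <- build_kernel(params, EY, mesh = length_mesh(params, n_bins = n_bins))
  pm <- population_metrics(K)
  out <- list(lam = pm$lam, xi = pm$xi, w_sum = sum(pm$w), ok = FALSE)
  der <- tryCatch(fundamental_and_nextgen(K), error = function(e) NULL)
  if (is.null(der) || pm$lam == 0) return(out)
  led <- life_expectancy_decomposition(der$N, K$mesh, params)
  sched <- age_schedules(K, x_max = 5000, tol = 1e-9)
  out$R0_eigen <- net_reproductive_rate(der)
  out$R0_sum <- sum(sched$l_x * sched$m_x)
  out$T <- generation_time(pm$lam, out$R0_eigen)
  out$eta_e <- led$eta_e
  out$L_alpha <- led$L_alpha
  out$L_omega <- led$L_omega
  out$ok <- TRUE
  out
}

# 100 synthetic species evaluated at both study feeding levels; computed
# once and shared across acceptance blocks
synthetic_demography_sweep <- function() {
  if (!is.null(.acc_cache$sweep)) return(.acc_cache$sweep)
  sp <- sample_deb_params(100, seed = 42)
  params <- attr(sp, "params")
  rows <- list()
  for (p in params)
    for (f in c(0.6, 0.9))
      rows[[paste0(p$species, "_", f)]] <- c(list(species = p$species,
                                                  EY = f, params = p),
                                             kernel_demography(p, f))
  .acc_cache$sweep <- rows
  rows
}
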