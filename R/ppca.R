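#' Expand a species tree to population tips
#'
#' Species represented by more than one population (e.g. the same species
#' modelled at two feeding levels) get their tip replaced by a dichotomous
#' cherry whose child branches have length `eps` (a tiny fraction of tree
#' height), so every population is a distinct tip while duplicates share
#' essentially their full evolutionary history.
#'
#' @param tree an `ape::phylo` with species as tip labels.
#' @param populations character vector of population labels of the form
#'   `"<species>|<id>"` or a data.frame with columns `species` and `pop`.
#' @param eps_frac cherry branch length as a fraction of tree height.
#' @return A `phylo` whose tips are the population labels.
#' @export
attach_population_tips <- function(tree, populations, eps_frac = 1e-6) {
  if (is.data.frame(populations)) {
    sp <- as.character(populations$species)
    pop <- as.character(populations$pop)
  } else {
    sp <- sub("\\|.*$", "", populations)
    pop <- as.character(populations)
  }
  missing_sp <- setdiff(unique(sp), tree$tip.label)
  if (length(missing_sp))
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  height <- max(ape::node.depth.edgelength(tree))
  eps <- eps_frac * height
  for (s in unique(sp)) {
    pops <- pop[sp == s]
    tip <- which(tree$tip.label == s)
    if (length(pops) == 1L) {
      tree$tip.label[tip] <- pops
      next
    }
    e <- which(tree$edge[, 2] == tip)
    # keep tip depth: the grafted cherry adds eps (root edge) + eps (child)
    tree$edge.length[e] <- max(tree$edge.length[e] - 2 * eps, eps)
    cherry <- ape::read.tree(text = paste0(
      "(", paste0(pops, ":", format(eps, scientific = FALSE), collapse = ","),
      "):", format(eps, scientific = FALSE), ";"))
    tree <- ape::bind.tree(tree, cherry, where = which(tree$tip.label == s))
  }
  extra <- setdiff(tree$tip.label, pop)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree
}

#' Brownian-motion covariance of a phylogeny
#'
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j` —
#' the among-tip covariance of a trait evolving by Brownian motion.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda` while keeping the
#' diagonal: `lambda = 1` leaves `C` unchanged (full Brownian signal),
#' `lambda = 0` yields independence.
#'
#' @param C covariance matrix from [phylo_covariance()].
#' @param lambda scaling in \[0, 1\].
#' @export
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles, for each candidate lambda in \[0, 1\], the multivariate-normal
#' log-likelihood of every trait column under the lambda-transformed
#' covariance with a GLS mean and profiled variance, sums the per-trait
#' log-likelihoods, and maximizes over lambda by one-dimensional bounded
#' optimization.
#'
#' @param X numeric matrix: rows = tips (ordered as `C`), columns = traits.
#' @param C phylogenetic covariance from [phylo_covariance()].
#' @return List with `lambda` (the ML estimate) and `logLik` at the optimum.
#' @export
pagel_lambda_ml <- function(X, C) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != nrow(C)) stop("rows of X must match C")
  negll <- function(lambda) {
    Cl <- lambda_transform(C, lambda)
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    ones <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    total <- 0
    for (k in seq_len(ncol(X))) {
      x <- X[, k]
      Cx <- backsolve(ch, forwardsolve(t(ch), x))
      ahat <- sum(Cx) / sum(ones)
      r <- x - ahat
      Cr <- backsolve(ch, forwardsolve(t(ch), r))
      s2 <- sum(r * Cr) / n
      if (s2 <= 0) return(1e10)
      total <- total + (-n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2)
    }
    -total
  }
  opt <- stats::optimize(negll, interval = c(0, 1), tol = 1e-6)
  # the interior optimum can sit at a boundary; compare explicitly
  cand <- c(opt$minimum, 0, 1)
  vals <- c(opt$objective, negll(0), negll(1))
  best <- which.min(vals)
  list(lambda = cand[best], logLik = -vals[best])
}

#' Residualize traits on body mass
#'
#' Replaces each trait column by the residuals of an ordinary least-squares
#' regression on log10 body mass, then re-scales the residual columns to
#' mean 0 and sd 1. Removes the allometric size signal before ordination.
#'
#' @param X numeric matrix of (log-transformed, scaled) traits; rows =
#'   populations.
#' @param mass per-population body mass (same length as `nrow(X)`, > 0).
#' @param log_mass take log10 of `mass` first (default TRUE, the
#'   allometric standard).
#' @return Matrix of standardized residual traits.
#' @export
mass_correct <- function(X, mass, log_mass = TRUE) {
  X <- as.matrix(X)
  if (length(mass) != nrow(X)) stop("mass must have one value per row of X")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be positive")
  m <- if (log_mass) log10(mass) else mass
  if (stats::sd(m) == 0) stop("constant mass: degenerate regression")
  res <- apply(X, 2, function(x) stats::residuals(stats::lm(x ~ m)))
  scale(res)[, , drop = FALSE]
}

#' Phylogenetically corrected principal component analysis
#'
#' Computes the GLS (evolutionary) mean of each trait under the supplied
#' covariance, forms the evolutionary trait covariance
#' `R = (X - 1a)' C^{-1} (X - 1a) / (n - 1)`, eigen-decomposes it, and
#' projects the centred data on the eigenvectors. With `C = I` this
#' reduces to ordinary PCA.
#'
#' @param X numeric matrix: rows = populations (ordered as `C`), columns =
#'   traits.
#' @param C (lambda-transformed) phylogenetic covariance; identity for an
#'   ordinary PCA.
#' @return List with `eigenvalues`, `eigenvectors`, `loadings`
#'   (eigenvectors scaled by sqrt eigenvalue), `scores`, `gls_mean`,
#'   `var_prop`, `cum_var`.
#' @export
ppca <- function(X, C = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(C)) C <- diag(n)
  ch <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is singular or not positive definite"))
  Cinv_X <- backsolve(ch, forwardsolve(t(ch), X))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- colSums(Cinv_X) / sum(Cinv_1)
  Xc <- sweep(X, 2, a)
  Rev <- crossprod(Xc, backsolve(ch, forwardsolve(t(ch), Xc))) / (n - 1)
  eg <- eigen(Rev, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  vec <- eg$vectors
  dimnames(vec) <- list(colnames(X), paste0("PC", seq_along(ev)))
  loadings <- sweep(vec, 2, sqrt(ev), "*")
  scores <- Xc %*% vec
  list(eigenvalues = ev, eigenvectors = vec, loadings = loadings,
       scores = scores, gls_mean = a,
       var_prop = ev / sum(ev), cum_var = cumsum(ev) / sum(ev))
}

#' Kaiser retention rule
#'
#' Retain axes whose eigenvalue exceeds unity.
#'
#' @param eigenvalues eigenvalues sorted in decreasing order.
#' @return Logical vector of retained-axis flags; warns when none pass.
#' @export
kaiser_retain <- function(eigenvalues) {
  keep <- eigenvalues > 1
  if (!any(keep)) warning("no axis passes the Kaiser criterion")
  keep
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal (Kaiser-normalized) varimax rotation of the retained loading
#' columns towards simple structure; scores are rotated by the same
#' orthogonal matrix, so row communalities are preserved.
#'
#' @param loadings loadings matrix (traits x axes, sqrt-eigenvalue scaled).
#' @param scores scores matrix (populations x axes) on the same axes.
#' @param retained logical flags from [kaiser_retain()].
#' @return List with `loadings` (rotated, retained axes only), `scores`
#'   (rotated), `rotmat`, and `ss_loadings` (sum-of-squares per rotated
#'   axis).
#' @export
varimax_rotate <- function(loadings, scores, retained = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, ncol(loadings))
  L <- loadings[, retained, drop = FALSE]
  Sc <- scores[, retained, drop = FALSE]
  if (ncol(L) < 2) {
    return(list(loadings = L, scores = Sc,
                rotmat = diag(ncol(L)), ss_loadings = colSums(L^2)))
  }
  vr <- stats::varimax(L, normalize = TRUE)
  R <- vr$rotmat
  Lr <- L %*% R
  colnames(Lr) <- paste0("RC", seq_len(ncol(Lr)))
  Sr <- Sc %*% R
  colnames(Sr) <- colnames(Lr)
  list(loadings = Lr, scores = Sr, rotmat = R, ss_loadings = colSums(Lr^2))
}

#' Pearson correlation between feeding level and axis scores
#'
#' @param scores numeric vector of PC scores, one per population.
#' @param feeding_levels matching vector of feeding levels.
#' @return List with `r`, `df` (`n - 2`) and the two-sided `p` from the
#'   t transform.
#' @export
feeding_correlation <- function(scores, feeding_levels) {
  if (length(scores) != length(feeding_levels))
    stop("scores and feeding levels must match")
  if (length(scores) < 3) stop("need at least 3 populations")
  if (stats::sd(scores) == 0 || stats::sd(feeding_levels) == 0)
    stop("zero variance in scores or feeding levels")
  ct <- stats::cor.test(scores, feeding_levels)
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Log-transform and standardize a trait table for ordination
#'
#' Takes log10 of each trait (adding a machine-safe offset of 1e-10 to
#' zero cells, which are flagged) and z-scores each column. Rows with any
#' missing trait are dropped and reported.
#'
#' @param traits data.frame from [trait_table()] (persistent rows only are
#'   recommended).
#' @param trait_cols trait columns to use.
#' @return List with matrix `X` (rows named `"<species>|<EY>"`), the kept
#'   `rows` of the input, and counts of `zero_cells` and `dropped_rows`.
#' @export
prepare_trait_matrix <- function(traits,
                                 trait_cols = c("T", "L_alpha", "gamma",
                                                "rho", "phi", "S_itero",
                                                "R0", "L_omega")) {
  M <- as.matrix(traits[, trait_cols])
  M[!is.finite(M)] <- NA
  complete <- stats::complete.cases(M)
  dropped <- sum(!complete)
  M <- M[complete, , drop = FALSE]
  zero_cells <- sum(M == 0, na.rm = TRUE)
  M[M == 0] <- 1e-10
  if (any(M < 0)) stop("negative trait values cannot be log-transformed")
  X <- scale(log10(M))
  rownames(X) <- paste0(traits$species[complete], "|", traits$EY[complete])
  list(X = X[, , drop = FALSE], rows = traits[complete, , drop = FALSE],
       zero_cells = zero_cells, dropped_rows = dropped)
}

#' Comparative analysis: phylogenetic varimax PCA of a trait table
#'
#' End-to-end comparative layer: standardizes the trait table, expands the
#' species tree to population tips, estimates Pagel's lambda by maximum
#' likelihood, runs the phylogenetically corrected PCA under the
#' lambda-transformed covariance, retains axes by the Kaiser criterion,
#' varimax-rotates them, labels the retained axis loading most strongly on
#' recruitment success, iteroparity and net reproductive rate as
#' `"reproductive_output"` (sign-fixed so recruitment success loads
#' negatively) and the other as `"generation_turnover"` (sign-fixed so
#' progressive growth loads negatively), and correlates each retained
#' axis with feeding level.
#'
#' @param traits data.frame from [trait_table()]; only rows with
#'   `persistent == TRUE` enter the analysis.
#' @param tree species-level `ape::phylo`; tips must cover all persistent
#'   species.
#' @param mass optional named per-species body mass (g); when supplied the
#'   traits are mass-corrected ([mass_correct()]) and species without mass
#'   are dropped.
#' @param eps_frac duplicate-tip branch length fraction.
#' @return Object of class `"deb_ppca"`: list with `lambda_P`,
#'   `eigenvalues`, `var_prop`, `cum_var`, `retained`, `loadings` (rotated),
#'   `scores` (rotated, with axis labels), `axis_labels`,
#'   `feeding_cor` (per retained axis), `populations`, `n_populations`,
#'   `n_species`, and the unrotated `raw` fit.
#' @export
comparative_analysis <- function(traits, tree, mass = NULL, eps_frac = 1e-6) {
  keep <- traits[traits$persistent %in% TRUE, , drop = FALSE]
  if (!is.null(mass)) {
    keep <- keep[keep$species %in% names(mass)[is.finite(mass) & mass > 0], ,
                 drop = FALSE]
  }
  prep <- prepare_trait_matrix(keep)
  X <- prep$X
  rows <- prep$rows
  pops <- data.frame(species = rows$species,
                     pop = rownames(X), stringsAsFactors = FALSE)
  ptree <- attach_population_tips(tree, pops, eps_frac = eps_frac)
  C <- phylo_covariance(ptree)
  X <- X[match(rownames(C), rownames(X)), , drop = FALSE]
  rows <- rows[match(rownames(C), paste0(rows$species, "|", rows$EY)), ,
               drop = FALSE]
  if (!is.null(mass)) {
    X <- mass_correct(X, unname(mass[rows$species]))
    rownames(X) <- rownames(C)
  }
  lam_fit <- pagel_lambda_ml(X, C)
  Cl <- lambda_transform(C, lam_fit$lambda)
  fit <- ppca(X, Cl)
  # Kaiser rule on correlation-matrix scale: the evolutionary covariance
  # carries the tree-height scale, so rescale eigenvalues to sum to the
  # trait count before comparing against unity
  kaiser_vals <- fit$eigenvalues / sum(fit$eigenvalues) *
    length(fit$eigenvalues)
  retained <- kaiser_retain(kaiser_vals)
  rot <- varimax_rotate(fit$loadings, fit$scores, retained)

  # axis identity: reproductive-output block = phi, S_itero, R0
  repro_block <- intersect(c("phi", "S_itero", "R0"), rownames(rot$loadings))
  labels <- rep("axis", ncol(rot$loadings))
  if (ncol(rot$loadings) >= 2) {
    strength <- colSums(abs(rot$loadings[repro_block, , drop = FALSE]))
    repro_axis <- which.max(strength)
    labels[repro_axis] <- "reproductive_output"
    labels[-repro_axis][1] <- "generation_turnover"
    # sign conventions: phi negative on the reproductive axis,
    # gamma negative on the turnover axis
    flip <- rep(1, ncol(rot$loadings))
    if (rot$loadings["phi", repro_axis] > 0) flip[repro_axis] <- -1
    turn_axis <- which(labels == "generation_turnover")
    if (rot$loadings["gamma", turn_axis] > 0) flip[turn_axis] <- -1
    rot$loadings <- sweep(rot$loadings, 2, flip, "*")
    rot$scores <- sweep(rot$scores, 2, flip, "*")
  } else if (ncol(rot$loadings) == 1) {
    labels <- "axis1"
  }
  colnames(rot$loadings) <- labels
  colnames(rot$scores) <- labels

  feeding_cor <- lapply(seq_len(ncol(rot$scores)), function(k)
    tryCatch(feeding_correlation(rot$scores[, k], rows$EY),
             error = function(e) list(r = NA_real_, df = NA_real_,
                                      p = NA_real_)))
  names(feeding_cor) <- labels

  out <- list(lambda_P = lam_fit$lambda, eigenvalues = fit$eigenvalues,
              kaiser_values = kaiser_vals,
              var_prop = fit$var_prop, cum_var = fit$cum_var,
              retained = retained, loadings = rot$loadings,
              scores = rot$scores, axis_labels = labels,
              rotmat = rot$rotmat, feeding_cor = feeding_cor,
              populations = rows, n_populations = nrow(X),
              n_species = length(unique(rows$species)),
              mass_corrected = !is.null(mass), raw = fit, tree = ptree,
              C = C)
  class(out) <- "deb_ppca"
  out
}

#' @export
print.deb_ppca <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic PCA of %d populations (%d species)%s\n",
    x$n_populations, x$n_species,
    if (x$mass_corrected) ", mass-corrected" else ""))
  cat(sprintf("  Pagel's lambda = %.3f; retained axes: %d\n",
              x$lambda_P, sum(x$retained)))
  for (k in seq_len(min(3, length(x$var_prop))))
    cat(sprintf("  PC%d: %.1f%% of variance\n", k, 100 * x$var_prop[k]))
  for (nm in names(x$feeding_cor))
    cat(sprintf("  %s vs feeding level: r = %.3f (p = %.3g)\n",
                nm, x$feeding_cor[[nm]]$r, x$feeding_cor[[nm]]$p))
  invisible(x)
}
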