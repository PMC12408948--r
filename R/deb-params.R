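#' Energy-budget parameter set for one species
#'
#' Bundles the eight Kooijman-Metz parameters that define a species'
#' length-structured projection kernel: lengths at birth, maturation and
#' the asymptotic maximum (at feeding level 1), the von Bertalanffy growth
#' rate, the maximum reproduction rate, stage-specific mortality rates, and
#' the allocation fraction kappa that sets the starvation threshold.
#'
#' @param L_b length at birth (cm).
#' @param L_p length at maturation (cm); must exceed `L_b`.
#' @param L_m maximum length reached at feeding level 1 (cm); must exceed `L_p`.
#' @param r_B von Bertalanffy growth rate (1/year).
#' @param R_m maximum reproduction rate at feeding level 1 (offspring/year).
#' @param mu_j juvenile instantaneous mortality rate (1/year).
#' @param mu_a adult instantaneous mortality rate (1/year).
#' @param kappa fraction of assimilated energy allocated to maintenance and
#'   growth; enters the model only through the starvation threshold
#'   `L_m * E(Y) / kappa`. Defaults to 0.8, the value used for most species
#'   in elasmobranch energy-budget compilations.
#' @param species optional species label.
#'
#' @return An object of class `"deb_params"` (a named list).
#' @examples
#' sp <- deb_params(L_b = 20, L_p = 50, L_m = 100, r_B = 0.3, R_m = 40,
#'                  mu_j = 0.2, mu_a = 0.15)
#' starvation_threshold(sp, 0.6)
#' @export
deb_params <- function(L_b, L_p, L_m, r_B, R_m, mu_j, mu_a, kappa = 0.8,
                       species = NA_character_) {
  p <- list(L_b = as.numeric(L_b), L_p = as.numeric(L_p),
            L_m = as.numeric(L_m), r_B = as.numeric(r_B),
            R_m = as.numeric(R_m), mu_j = as.numeric(mu_j),
            mu_a = as.numeric(mu_a), kappa = as.numeric(kappa),
            species = as.character(species))
  validate_deb_params(p)
  class(p) <- "deb_params"
  p
}

validate_deb_params <- function(p) {
  num <- c("L_b", "L_p", "L_m", "r_B", "R_m", "mu_j", "mu_a", "kappa")
  bad <- num[!vapply(p[num], function(x) is.numeric(x) && length(x) == 1 &&
                       is.finite(x), logical(1))]
  if (length(bad))
    stop("non-numeric or missing parameter(s): ", paste(bad, collapse = ", "))
  if (!(p$L_b > 0 && p$L_b < p$L_p && p$L_p < p$L_m))
    stop("length ordering violated: need 0 < L_b < L_p < L_m (got L_b=",
         p$L_b, ", L_p=", p$L_p, ", L_m=", p$L_m, ")")
  if (p$r_B <= 0) stop("r_B must be > 0")
  if (p$R_m < 0) stop("R_m must be >= 0")
  if (p$mu_j < 0 || p$mu_a < 0) stop("mortality rates must be >= 0")
  if (p$kappa <= 0 || p$kappa >= 1) stop("kappa must lie in (0, 1)")
  invisible(p)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("DEB parameter set", if (!is.na(x$species)) paste0("(", x$species, ")"),
      "\n")
  cat(sprintf("  lengths (cm): birth %.3g, maturation %.3g, maximum %.3g\n",
              x$L_b, x$L_p, x$L_m))
  cat(sprintf("  r_B %.3g /yr, R_m %.3g /yr, mu_j %.3g, mu_a %.3g, kappa %.3g\n",
              x$r_B, x$R_m, x$mu_j, x$mu_a, x$kappa))
  invisible(x)
}

check_feeding_level <- function(EY) {
  if (!is.numeric(EY) || length(EY) != 1 || !is.finite(EY) || EY < 0 || EY > 1)
    stop("feeding level E(Y) must be a single number in [0, 1]")
  EY
}

#' Read a species parameter table from CSV
#'
#' Expects columns `species, Lb, Lp, Lm, rB, Rm, mu_j, mu_a, kappa`
#' (case-insensitive; `L_b`-style aliases accepted). Lengths are in cm and
#' rates per year. A blank `kappa` defaults to 0.8. Rows violating the
#' parameter invariants are rejected with their line numbers.
#'
#' @param path path to a CSV file.
#' @return A data.frame with one validated row per species and an attribute
#'   `"params"`: a list of [deb_params()] objects.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("species file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(gsub("[._]", "", names(raw)))
  alias <- c(species = "species", lb = "Lb", lp = "Lp", lm = "Lm", rb = "rB",
             rm = "Rm", muj = "mu_j", mua = "mu_a", kappa = "kappa")
  missing_cols <- setdiff(setdiff(names(alias), "kappa"), names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(alias[missing_cols], collapse = ", "))
  out <- data.frame(species = as.character(raw$species),
                    Lb = raw$lb, Lp = raw$lp, Lm = raw$lm, rb = raw$rb,
                    Rm = raw$rm, mu_j = raw$muj, mu_a = raw$mua,
                    kappa = if ("kappa" %in% names(raw)) raw$kappa else NA,
                    stringsAsFactors = FALSE)
  out$kappa[is.na(out$kappa)] <- 0.8
  params <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    params[[i]] <- tryCatch(
      deb_params(out$Lb[i], out$Lp[i], out$Lm[i], out$rb[i], out$Rm[i],
                 out$mu_j[i], out$mu_a[i], out$kappa[i],
                 species = out$species[i]),
      error = function(e) stop("row ", i + 1L, " (", out$species[i], "): ",
                               conditionMessage(e), call. = FALSE))
  }
  names(params) <- out$species
  attr(out, "params") <- params
  out
}

#' Write a species parameter table to CSV
#'
#' Inverse of [read_species_csv()]; round-trips values at full precision.
#'
#' @param species_table data.frame as returned by [read_species_csv()] or
#'   [sample_deb_params()].
#' @param path output path.
#' @export
write_species_csv <- function(species_table, path) {
  utils::write.csv(as.data.frame(species_table)[, c("species", "Lb", "Lp",
                                                    "Lm", "rb", "Rm", "mu_j",
                                                    "mu_a", "kappa")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

species_params_list <- function(species_table) {
  p <- attr(species_table, "params")
  if (!is.null(p)) return(p)
  lapply(seq_len(nrow(species_table)), function(i)
    deb_params(species_table$Lb[i], species_table$Lp[i], species_table$Lm[i],
               species_table$rb[i], species_table$Rm[i],
               species_table$mu_j[i], species_table$mu_a[i],
               species_table$kappa[i], species = species_table$species[i]))
}
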