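#' Optical model for hemoglobin spectroscopy and fluorescence correction
#'
#' Bundles the wavelength-dependent extinction coefficients, reflectance
#' pathlengths and the two pathlength ratios that govern conversion of
#' reflectance to hemoglobin concentration changes and the hemodynamic
#' correction of raw fluorescence:
#' \itemize{
#'   \item `Pg = X_ex(lambda_ex) / X_R(lambda_green)`: ratio of the distance
#'     traveled by the (lime) excitation light to the green-reflectance
#'     pathlength;
#'   \item `Pr = X_em(lambda_em) / X_R(lambda_red)`: ratio of the (red)
#'     emission pathlength to the red-reflectance pathlength.
#' }
#'
#' @param epsilon_hbo,epsilon_hbr extinction coefficients of oxy-/deoxy-
#'   hemoglobin in 1/(uM mm), one value per reflectance wavelength, named
#'   `green` and `red`.
#' @param X_R_green,X_R_red mean reflectance photon pathlengths in mm.
#' @param Pg,Pr pathlength ratios (dimensionless, `>= 0`).
#' @param wavelengths_nm informational wavelengths.
#' @return object of class `optical_model`.
#' @seealso [default_optics()], [convert_hemoglobin()], [correct_fluorescence()]
#' @export
optical_model <- function(epsilon_hbo, epsilon_hbr, X_R_green, X_R_red,
                          Pg = 0.25, Pr = 1.4,
                          wavelengths_nm = c(green = 530, red = 625)) {
  stopifnot_scalar_pos(X_R_green, "X_R_green")
  stopifnot_scalar_pos(X_R_red, "X_R_red")
  if (Pg < 0 || Pr < 0) stop("Pg and Pr must be >= 0", call. = FALSE)
  eps <- rbind(green = c(hbo = epsilon_hbo[["green"]], hbr = epsilon_hbr[["green"]]),
               red   = c(hbo = epsilon_hbo[["red"]],   hbr = epsilon_hbr[["red"]]))
  if (any(eps <= 0)) stop("extinction coefficients must be positive", call. = FALSE)
  X <- c(green = X_R_green, red = X_R_red)
  M <- eps * X                      # 2x2 system matrix [eps * X_R]
  if (abs(det(M)) < 1e-14)
    stop("extinction/pathlength matrix is singular; hemoglobin species are not separable",
         call. = FALSE)
  structure(list(epsilon = eps, X_R = X, M = M, Minv = solve(M),
                 Pg = Pg, Pr = Pr, wavelengths_nm = wavelengths_nm),
            class = "optical_model")
}

#' Default optical constants
#'
#' Extinction coefficients are compilation values in the style of the Prahl
#' tabulated hemoglobin spectra at 530 nm (green reflectance / lime
#' excitation band) and 625 nm (red reflectance / emission band), converted
#' to 1/(uM mm); reflectance pathlengths are Monte-Carlo-scale estimates for
#' mouse cortex. All values are configuration with override hooks
#' ([optical_model()], [read_optics_yaml()]); the algorithms, not these
#' constants, are the substance, and none of them is asserted as a measured
#' property of any specific preparation.
#'
#' @param Pg,Pr pathlength ratios; the defaults sit inside the plausible
#'   ranges for this preparation (Pg 0.2-0.3, Pr 1.1-1.8).
#' @return an `optical_model`.
#' @export
default_optics <- function(Pg = 0.25, Pr = 1.4) {
  ## molar extinction (1/(M cm)) * ln(10) * 1e-7 -> 1/(uM mm)
  k <- log(10) * 1e-7
  optical_model(
    epsilon_hbo = c(green = 39036 * k, red = 683 * k),
    epsilon_hbr = c(green = 39555 * k, red = 6510 * k),
    X_R_green = 0.5, X_R_red = 4.0,
    Pg = Pg, Pr = Pr
  )
}

#' Read / write optical constants as YAML
#'
#' @param path file path.
#' @return for `read_optics_yaml`, an `optical_model`.
#' @export
read_optics_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  optical_model(
    epsilon_hbo = unlist(y$epsilon_hbo), epsilon_hbr = unlist(y$epsilon_hbr),
    X_R_green = y$X_R_green, X_R_red = y$X_R_red,
    Pg = y$Pg %||% 0.25, Pr = y$Pr %||% 1.4,
    wavelengths_nm = unlist(y$wavelengths_nm %||% c(green = 530, red = 625))
  )
}

#' @rdname read_optics_yaml
#' @param optics an `optical_model`.
#' @export
write_optics_yaml <- function(optics, path) {
  yaml::write_yaml(list(
    epsilon_hbo = as.list(optics$epsilon[, "hbo"]),
    epsilon_hbr = as.list(optics$epsilon[, "hbr"]),
    X_R_green = unname(optics$X_R["green"]), X_R_red = unname(optics$X_R["red"]),
    Pg = optics$Pg, Pr = optics$Pr,
    wavelengths_nm = as.list(optics$wavelengths_nm)
  ), path, precision = 12)
  invisible(path)
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model (modified Beer-Lambert)\n")
  cat(sprintf("  wavelengths: green %g nm, red %g nm\n",
              x$wavelengths_nm[["green"]], x$wavelengths_nm[["red"]]))
  cat(sprintf("  X_R: green %.3g mm, red %.3g mm;  Pg = %.3g, Pr = %.3g\n",
              x$X_R[["green"]], x$X_R[["red"]], x$Pg, x$Pr))
  invisible(x)
}
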