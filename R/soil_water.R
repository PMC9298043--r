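#' Layered soil profile with stress parameters
#'
#' Describes the root-zone soil column used to compute the soil water
#' stress factor: per-layer field capacity (critical water content),
#' wilting point and root mass fraction, plus the stress-onset parameter
#' `p_0` delaying the onset of water stress below field capacity.
#'
#' @param theta_c field capacity per layer, m3 m-3.
#' @param theta_w wilting point per layer, m3 m-3.
#' @param root_frac root mass fraction per layer; must sum to 1.
#' @param p_0 stress-onset parameter in \[0, 1\] (default 0.4).
#' @return object of class `soil_profile`.
#' @export
#' @examples
#' sp <- soil_profile()           # 14 uniform layers
#' profile_stress(sp, rep(0.3, 14))  # saturated -> 1
soil_profile <- function(theta_c = rep(0.3, 14), theta_w = rep(0.1, 14),
                         root_frac = NULL, p_0 = 0.4) {
  n <- length(theta_c)
  if (is.null(root_frac)) {
    # exponential root distribution, deeper layers hold less root mass
    w <- exp(-0.35 * seq_len(n))
    root_frac <- w / sum(w)
  }
  stopifnot(length(theta_w) == n, length(root_frac) == n)
  if (any(theta_w >= theta_c)) stop("wilting point must be below field capacity")
  if (p_0 < 0 || p_0 > 1) stop("p_0 must lie in [0, 1]")
  if (abs(sum(root_frac) - 1) > 1e-6) stop("root fractions must sum to 1")
  structure(list(n_soil = n, theta_c = theta_c, theta_w = theta_w,
                 root_frac = root_frac, p_0 = p_0),
            class = "soil_profile")
}

#' Read a layered soil profile from a delimited file
#'
#' Expects one row per layer with columns `theta_c`, `theta_w` and
#' `root_frac` (field capacity, wilting point, root mass fraction).
#'
#' @param path CSV file path.
#' @param p_0 stress-onset parameter (default 0.4).
#' @return a [soil_profile()].
#' @export
read_soil_profile <- function(path, p_0 = 0.4) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("theta_c", "theta_w", "root_frac")
  if (!all(req %in% names(tab)))
    stop("soil profile file missing columns: ",
         paste(setdiff(req, names(tab)), collapse = ", "))
  soil_profile(theta_c = tab$theta_c, theta_w = tab$theta_w,
               root_frac = tab$root_frac, p_0 = p_0)
}

#' Single-layer soil water stress factor
#'
#' Piecewise-linear stress response: 1 above the upper threshold
#' `theta_upp = theta_w + (1 - p_0)(theta_c - theta_w)`, 0 at or below the
#' wilting point, linear in between. Continuous in theta.
#'
#' @param theta volumetric water content, m3 m-3 (vectorised).
#' @param theta_c field capacity, m3 m-3.
#' @param theta_w wilting point, m3 m-3.
#' @param p_0 stress-onset parameter.
#' @return stress factor beta_k in \[0, 1\].
#' @export
layer_stress <- function(theta, theta_c, theta_w, p_0 = 0.4) {
  if (any(theta_w >= theta_c)) stop("wilting point must be below field capacity")
  theta_upp <- theta_w + (1 - p_0) * (theta_c - theta_w)
  pmin(pmax((theta - theta_w) / (theta_upp - theta_w), 0), 1)
}

#' Root-weighted soil water stress factor
#'
#' `beta_soil = sum_k r_k beta_k`: the per-layer stress factors weighted by
#' the root mass fraction in each layer.
#'
#' @param profile a [soil_profile()].
#' @param theta per-layer volumetric water content, m3 m-3 (length
#'   `profile$n_soil`).
#' @return beta_soil in \[0, 1\].
#' @export
profile_stress <- function(profile, theta) {
  if (length(theta) != profile$n_soil)
    stop("theta must have one value per soil layer")
  beta_k <- layer_stress(theta, profile$theta_c, profile$theta_w, profile$p_0)
  sum(profile$root_frac * beta_k)
}
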