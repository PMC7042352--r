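#' Read a simulation configuration file
#'
#' Reads a YAML or JSON configuration with (all optional) sections
#' `tissue` (dimensional thermal properties, keys as in
#' [tissue_properties()]), `mechanical` (`lambda_l`, `mu_l`, `gamma_c`,
#' `T_0`), `dimensionless_override` (`beta1`, `beta2`, `beta3`, `Q`, `tau_q`,
#' `tau_T`, `L` — these bypass the dimensional route), `loading` (keys as in
#' [thermal_loading()]) and `numerics` (keys as in [inversion_options()],
#' plus `t`, `nx`).
#'
#' @param path file path; `.yml`/`.yaml` parsed with \pkg{yaml}, anything
#'   else with \pkg{jsonlite}.
#' @return A list with components `params` ([dpl_params()]), `loading`
#'   ([thermal_loading()]), `inversion` ([inversion_options()]), `t`
#'   (evaluation time, default 0.05) and `x_grid`.
#' @export
read_dpl_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  props <- do.call(tissue_properties,
                   c(as.list(cfg$tissue), as.list(cfg$mechanical)))
  ov <- as.list(cfg$dimensionless_override)
  params <- do.call(dpl_params, c(
    ov[names(ov) %in% c("beta1", "beta2", "beta3", "Q", "tau_q", "tau_T", "L")],
    list(properties = props)))
  loading <- if (is.null(cfg$loading)) thermal_loading("thermal_shock")
    else do.call(thermal_loading, cfg$loading)
  num <- as.list(cfg$numerics)
  inv_keys <- num[names(num) %in% c("kappa_t_product", "n_terms", "rel_tol",
                                    "max_terms", "chunk")]
  inversion <- do.call(inversion_options, inv_keys)
  t <- if (is.null(num$t)) 0.05 else num$t
  nx <- if (is.null(num$nx)) 121L else as.integer(num$nx)
  list(params = params, loading = loading, inversion = inversion,
       t = t, x_grid = seq(0, params$L, length.out = nx))
}
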