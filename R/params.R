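#' Model parameters
#'
#' Builds the full parameter set of the virtual-tumour model. Defaults are
#' the published parameter table of the model verbatim (diffusion,
#' production, decay and uptake rates), plus the lattice, threshold and
#' calibration constants that the published table does not cover. Every
#' field can be overridden by name, either here or through a YAML config
#' file (see [load_config()]).
#'
#' Two unit conventions deserve note (both exposed, both logged by the
#' driver):
#' \describe{
#' \item{`oxygen_rate_scale`}{The oxygen uptake rates `k_0`, `k_P`, `k_Q`
#'   and the vessel permeability scale `gamma_v_base` are printed in
#'   "per second" in the source table while all sibling rates are per
#'   hour; taken literally they are inconsistent with the oxygen
#'   diffusion coefficient (the implied capillary-field screening length
#'   \eqn{\sqrt{D_O/k_0}} would be under a micron). They are therefore
#'   stored verbatim and multiplied by `oxygen_rate_scale` (default 1/24,
#'   i.e. the printed number read as a per-day-equivalent rate on the
#'   normalized oxygen concentration) wherever they enter the dynamics.
#'   The default gives a screening length of 0.155 mm, in the
#'   physiological 100--200 um range.}
#' \item{`O_v`}{Oxygen is normalized so that intact tissue over the
#'   baseline capillary field sits at \eqn{O = 1}. The intravascular
#'   concentration is then fixed by the uniform steady state
#'   \eqn{O_v = (\gamma E_0 + k_0)/(\gamma E_0)} (effective rates), 1.5
#'   by default. Pass `O_v` explicitly to override.}
#' }
#'
#' @param ... named parameter overrides.
#' @param .validate logical; skip validation (internal use only).
#' @return An object of class `vt_params`: a named list of parameters.
#' @export
#' @examples
#' p <- model_params()
#' p$D_V              # 0.104 mm^2/h
#' model_params(grid_n = 50)$grid_n
model_params <- function(..., .validate = TRUE) {
  p <- list(
    ## -- diffusive species (published table, verbatim) ------------------
    D_V = 0.104,        # VEGF diffusion, mm^2/h
    D_O = 2.41e-3,      # oxygen diffusion, mm^2/h
    D_p = 1.73e-3,      # tumour-protease diffusion, mm^2/h
    D_m = 10.4e-3,      # sprout-protease diffusion, mm^2/h
    alpha_V = 0.0145,   # VEGF production by quiescent cells (per h equivalent)
    alpha_p = 3600,     # protease production by proliferative tumour cells, per h
    alpha_m = 130,      # protease production by sprout endothelium, per h
    nu_V = 0.65,        # VEGF decay, per h
    nu_p = 0.21,        # tumour-protease decay, per h
    nu_m = 1.30,        # sprout-protease decay, per h
    lambda_V = 1,       # VEGF consumption per unit vessel weight, per h
    V_max = 0.06,       # receptor-saturation cap on VEGF uptake, per h
    gamma_v_base = 4.8, # vessel permeability scale (x R/R_min), printed units
    k_0 = 2.4,          # oxygen uptake, normal tissue (printed units)
    k_P = 4.8,          # oxygen uptake, proliferative cells (2 k_0)
    k_Q = 2.4,          # oxygen uptake, quiescent cells (= k_0)
    oxygen_rate_scale = 1 / 24, # printed oxygen-group rates -> per-h effective
    O_v = NULL,         # intravascular O; NULL = fixed by normalization
    ## -- lattice and capillary field ------------------------------------
    grid_n = 200,       # lattice side, elements
    dx = 0.02,          # element size, mm (~ one tumour-cell diameter)
    E_0 = 1,            # baseline capillary density (dimensionless)
    ## -- thresholds (normalized O units; calibration values) ------------
    O_quiescence = 0.65, # below this, G1 cells arrest
    O_necrosis = 0.05,  # below this, living cells necrose
    V_sprout = 5e-3,    # VEGF level gating sprout initiation
    p_degrade = 4200,   # protease level destroying the capillary field
    ## -- cell cycle ------------------------------------------------------
    mu0 = 24,           # initial cell-cycle duration, h
    sigma_cycle = 0.2,  # SD of inherited cycle duration, h
    S_dur = 8, G2_dur = 4, M_dur = 1, # fixed phase durations, h (G1 = mu - 13)
    lysis_delay = 48,   # h a dead cell keeps occupying its element
    division_wait = 48, # h a blocked division-ready cell retries before apoptosis
    ## -- vasculature / angiogenesis (calibration values) -----------------
    R_min = 3,          # minimum vessel radius, um
    R_max = 150,        # maximum vessel radius, um
    R_neo = 12,         # radius assigned to neovessel segments, um
    seg_weight_scale = 0.5, # weight of one segment length-unit relative
                            # to an element's capillary bed (E_0) in the
                            # field coupling
    sprout_init_rate = 0.004,  # per h per eligible node at V = 2 V_sprout
    sprout_move_prob = 0.06,   # per h per active tip
    sprout_branch_prob = 0.12, # per step when V > 2 V_sprout
    sprout_spacing = 4,        # min Chebyshev spacing of origins, elements
    chemotaxis_kappa = 2000,   # tip direction bias per unit VEGF difference
    matrix_degrade_rate = 1e-3, # matrix integrity loss per unit m per h
    ## -- hemodynamics ----------------------------------------------------
    entry_pressure = 13,    # kPa at the reference-vessel entry node
    boundary_pressure = 2,  # kPa at domain-border vessel endpoints
    viscosity = 1,          # arbitrary consistent units (only ratios matter)
    adapt_tau_ref = 0.1,    # shear-stimulus offset
    adapt_k_met = 0.8,      # metabolic stimulus weight
    adapt_Q_ref = 1e5,      # metabolic reference flow (arbitrary units)
    adapt_k_shrink = 1.6,   # constant shrinking tendency
    adapt_step = 0.1,       # Euler step on log-radius per iteration
    adapt_tol = 1e-4,       # max relative diameter change at convergence
    adapt_max_iter = 5000,
    ## -- field integration -----------------------------------------------
    substep_safety = 0.9,   # fraction of the explicit stability limit
    oxygen_mode = "steady", # "steady" (quasi-steady) or "explicit"
    steady_tol = 1e-9,      # SOR residual tolerance (absolute, normalized O)
    vegf_weight_includes_E = TRUE, # capillaries consume VEGF too
    ## -- image initialization (calibration values) ------------------------
    fill_low = 0.3, fill_med = 0.6, fill_high = 0.9, # per-region occupancy
    init_noise_sd = 0.2,    # grey-level noise SD in the re-threshold step
    lcc_dilate = 2          # dilation radius for bulk-component selection
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(ov)] <- ov
  }
  if (is.null(p$O_v)) {
    g <- p$gamma_v_base * p$oxygen_rate_scale * p$E_0
    p$O_v <- (g + p$k_0 * p$oxygen_rate_scale) / g
  }
  class(p) <- "vt_params"
  if (.validate) validate_params(p)
  p
}

validate_params <- function(p) {
  num1 <- function(key) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", key, "' must be a single finite number",
           call. = FALSE)
    v
  }
  rates <- c("D_V", "D_O", "D_p", "D_m", "alpha_V", "alpha_p", "alpha_m",
             "nu_V", "nu_p", "nu_m", "lambda_V", "V_max", "gamma_v_base",
             "k_0", "k_P", "k_Q", "oxygen_rate_scale", "seg_weight_scale",
             "E_0", "sigma_cycle",
             "matrix_degrade_rate", "sprout_init_rate", "sprout_move_prob",
             "sprout_branch_prob")
  for (key in rates)
    if (num1(key) < 0)
      stop("parameter '", key, "' must be non-negative", call. = FALSE)
  for (key in c("dx", "mu0", "O_v", "viscosity"))
    if (num1(key) <= 0)
      stop("parameter '", key, "' must be positive", call. = FALSE)
  if (num1("grid_n") <= 0 || p$grid_n != round(p$grid_n))
    stop("grid_n must be a positive integer", call. = FALSE)
  if (!(p$k_P >= p$k_0 && p$k_0 >= p$k_Q))
    stop("oxygen uptake rates must satisfy k_P >= k_0 >= k_Q", call. = FALSE)
  if (num1("O_necrosis") >= num1("O_quiescence"))
    stop("O_necrosis must be below O_quiescence", call. = FALSE)
  if (num1("mu0") <= p$S_dur + p$G2_dur + p$M_dur)
    stop("mu0 must exceed the fixed S+G2+M phase time", call. = FALSE)
  if (!(num1("R_min") > 0 && p$R_min <= num1("R_neo") &&
        p$R_neo <= num1("R_max")))
    stop("vessel radii must satisfy 0 < R_min <= R_neo <= R_max",
         call. = FALSE)
  if (!p$oxygen_mode %in% c("steady", "explicit"))
    stop("oxygen_mode must be 'steady' or 'explicit'", call. = FALSE)
  invisible(p)
}

#' @export
print.vt_params <- function(x, ...) {
  cat("<vt_params> virtual-tumour model parameters\n")
  cat(sprintf("  lattice: %d x %d, dx = %g mm (%.1f x %.1f mm domain)\n",
              x$grid_n, x$grid_n, x$dx, x$grid_n * x$dx, x$grid_n * x$dx))
  keys <- setdiff(names(unclass(x)), c("grid_n", "dx"))
  vals <- vapply(keys, function(k) format(x[[k]]), character(1))
  cat(sprintf("  %-22s %s\n", keys, vals), sep = "")
  invisible(x)
}

#' Read a run configuration file
#'
#' Reads a flat key--value YAML file of parameter overrides and returns the
#' full parameter set, with the published defaults for every key not
#' present in the file.
#'
#' @param path path to a YAML file; a flat mapping of parameter names to
#'   scalar values.
#' @param quiet logical; suppress the effective-value log.
#' @return a [model_params()] object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("configuration parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg) || (length(cfg) && is.null(names(cfg))))
    stop("configuration must be a flat key-value mapping", call. = FALSE)
  p <- do.call(model_params, cfg)
  if (!quiet) {
    message("configuration '", basename(path), "': ",
            length(cfg), " override(s); effective values:")
    for (k in names(unclass(p)))
      message(sprintf("  %-22s %s", k, format(p[[k]])))
  }
  p
}

#' Write a parameter set to a configuration file
#'
#' The written file round-trips: `load_config(save_config(p, f))` restores
#' identical parameter values.
#'
#' @param params a [model_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "vt_params"))
  yaml::write_yaml(unclass(params), path, precision = 17L)
  invisible(path)
}

#' Moore neighbourhood of a lattice element
#'
#' Returns the coordinates of the up-to-8 elements surrounding `(i, j)` on
#' an `n x n` lattice, clipped at the domain boundary (3 at a corner, 5 on
#' an edge, 8 in the interior).
#'
#' @param i,j element indices in `1..n`.
#' @param n lattice side.
#' @return a two-column integer matrix of `(i, j)` coordinates.
#' @export
neighbours8 <- function(i, j, n) {
  if (i < 1 || i > n || j < 1 || j > n)
    stop("index (", i, ", ", j, ") outside the ", n, " x ", n, " lattice",
         call. = FALSE)
  di <- rep(-1:1, times = 3)
  dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ni <- i + di[keep]; nj <- j + dj[keep]
  ok <- ni >= 1 & ni <= n & nj >= 1 & nj <= n
  cbind(i = ni[ok], j = nj[ok])
}

#' Symbol table of the model equations
#'
#' Maps every symbol of the reaction--diffusion system and of the
#' vessel-weight formula to the parameter or grid field that implements
#' it. Each symbol maps to exactly one field.
#'
#' @return a data frame with columns `symbol`, `equation` and `field`.
#' @export
param_symbol_table <- function() {
  tab <- rbind(
    c("D_V",      "reaction-diffusion", "D_V"),
    c("D_O",      "reaction-diffusion", "D_O"),
    c("D_p",      "reaction-diffusion", "D_p"),
    c("D_m",      "reaction-diffusion", "D_m"),
    c("alpha_V",  "reaction-diffusion", "alpha_V"),
    c("alpha_p",  "reaction-diffusion", "alpha_p"),
    c("alpha_m",  "reaction-diffusion", "alpha_m"),
    c("nu_V",     "reaction-diffusion", "nu_V"),
    c("nu_p",     "reaction-diffusion", "nu_p"),
    c("nu_m",     "reaction-diffusion", "nu_m"),
    c("lambda_V", "reaction-diffusion", "lambda_V"),
    c("V_max",    "reaction-diffusion", "V_max"),
    c("gamma_v",  "reaction-diffusion", "gamma_v_base"),
    c("O_v",      "reaction-diffusion", "O_v"),
    c("k_0",      "reaction-diffusion", "k_0"),
    c("k_P",      "reaction-diffusion", "k_P"),
    c("k_Q",      "reaction-diffusion", "k_Q"),
    c("Q_ij",     "reaction-diffusion", "grid: quiescent-cell indicator"),
    c("P_ij",     "reaction-diffusion", "grid: proliferative-cell indicator"),
    c("n_ij",     "reaction-diffusion", "grid: active-sprout-edge indicator"),
    c("W_ij",     "vessel weight",      "grid: vessel weight (derived)"),
    c("L_b",      "vessel weight",      "dx"),
    c("L_d",      "vessel weight",      "dx (x sqrt(2))"),
    c("E_ij",     "vessel weight",      "grid: capillary density E")
  )
  data.frame(symbol = tab[, 1], equation = tab[, 2], field = tab[, 3],
             stringsAsFactors = FALSE)
}

## effective (per-hour) oxygen-group rates
oxy_rates <- function(p) {
  s <- p$oxygen_rate_scale
  list(k_0 = p$k_0 * s, k_P = p$k_P * s, k_Q = p$k_Q * s,
       gamma = p$gamma_v_base * s)
}
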