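#' Default run configuration
#'
#' A flat named list covering every model parameter (by its conventional
#' symbol), the protocol fields, the variant and the integrator settings.
#' [load_config()] starts from these defaults and overrides the keys present
#' in the user's file; unknown keys are rejected.
#'
#' The `seed` field is accepted for interface completeness; the model is
#' fully deterministic and the seed is never consumed.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    ## calcium channel voltage dependence
    alpha = 4, d = 0.4, lambda = 0.5,
    ## potassium channel voltage dependence
    alpha_K = 0.5, d_K = 0.5, lambda_K = 0.005,
    ## hyperpolarisation-activated family
    alpha_h = 4, d_h = 1, lambda_h = 5,
    ## cilium-to-body family
    alpha_t = -4, d_t = 1, lambda_t = 5,
    ## gating
    k = 2, kC = 1, cac0 = 20,
    ## pump and calcium pools
    kA = 1, uout = 1000, ut = 0.025,
    ## flux / conductance groups
    b = 2, b1 = 1, s = 0.5, a = 4, rho = 10,
    nu_Ca_st = 0.01, nu_K_st = 0.01,
    vCah = 0, vKca = 0, vCat = 0,
    ## potentials
    psi0 = -1.2, psi1 = 0.5, psiK = -2, psi_tr = 0,
    ## protocol
    tau0 = 0.02, tauK = 0.02, duration = 40,
    mechanism = "direct", include_K = FALSE,
    variant = "base", I0 = 0,
    ## which simulator run_preset() drives: "clamp" or "free"
    run = "clamp",
    ## units
    K_CaM = 4, RT_over_F = -0.025,
    ## integrator
    rtol = 1e-8, atol = 1e-10, n_out = 2001,
    ## interface completeness; the model is deterministic
    seed = NULL
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, checks every key against [default_config()] (unknown
#' keys raise an error that lists them), and returns the defaults overridden
#' by the file's values. The provenance of each key (`"default"` or
#' `"user"`) is attached as an attribute.
#'
#' @param path Path to a YAML configuration file. An empty file yields the
#'   full defaults.
#' @return A validated configuration list with attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  prov <- stats::setNames(rep("default", length(defaults)), names(defaults))
  prov[names(user)] <- "user"
  attr(cfg, "provenance") <- prov
  cfg
}

#' Figure presets
#'
#' Named parameter bundles reproducing the model's published figure
#' settings. `preset_names()` lists them; `figure_preset()` returns the
#' full configuration (defaults overridden by the preset).
#'
#' @param name Preset name, one of `preset_names()`.
#' @return A configuration list (same shape as [default_config()]).
#' @export
figure_preset <- function(name) {
  presets <- list(
    ## steady-state curve and direct-clamp spikes
    fig2 = list(mechanism = "direct", b = 2, s = 0.5, k = 2),
    fig3 = list(mechanism = "direct", b = 2, s = 0.5, k = 2,
                psi0 = -1.2, psi1 = 0.5),
    ## indirect clamp, sensor-abundance series
    fig5 = list(mechanism = "indirect", b = 2, a = 4, kC = 1, cac0 = 20,
                psi0 = -1.2, psi1 = 0.5),
    fig7 = list(mechanism = "indirect", b = 2, a = 4, kC = 1, cac0 = 20),
    ## clamp with the potassium current included
    fig9 = list(mechanism = "direct", b = 2, b1 = 1, include_K = TRUE),
    ## free-membrane current responses
    fig10 = list(run = "free", variant = "base", b = 8, cac0 = 20, rho = 10,
                 s = 0.5, nu_Ca_st = 0.01, nu_K_st = 0.01, duration = 200),
    ## coupled system regimes
    fig11 = list(run = "free", variant = "base", b = 8, cac0 = 20, rho = 10,
                 s = 0.5, nu_Ca_st = 0.01, nu_K_st = 0.01, I0 = 0.2,
                 duration = 400),
    fig12 = list(run = "free", variant = "hyper", b = 8, cac0 = 20, rho = 10,
                 s = 0.5, nu_Ca_st = 0.01, nu_K_st = 0.01, vCah = 0.9,
                 alpha_h = 4, d_h = 1, lambda_h = 5, I0 = 0.5,
                 duration = 400),
    fig13 = list(run = "free", variant = "hyper", b = 8, cac0 = 20, rho = 10,
                 s = 0.5, nu_Ca_st = 0.01, nu_K_st = 0.01, vCah = 0.9, I0 = 1,
                 duration = 400),
    fig14 = list(run = "free", variant = "full", b = 8, cac0 = 20, rho = 10,
                 s = 0.5, nu_Ca_st = 0.01, nu_K_st = 0.01, vCah = 0.9,
                 vCat = 0.1, duration = 400)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  utils::modifyList(default_config(), presets[[name]])
}

#' @rdname figure_preset
#' @export
preset_names <- function() {
  c("fig2", "fig3", "fig5", "fig7", "fig9", "fig10", "fig11", "fig12",
    "fig13", "fig14")
}

#' Build model objects from a configuration
#'
#' @param config A configuration list ([default_config()] shape).
#' @return `as_clamp_params` / `as_coupled_params` / `as_clamp_protocol`
#'   return the corresponding parameter objects.
#' @export
as_clamp_params <- function(config) {
  mech <- match.arg(config$mechanism, c("direct", "indirect"))
  gating <- if (mech == "direct") direct_gating(k = config$k)
            else indirect_gating(kC = config$kC, cac0 = config$cac0)
  clamp_params(mechanism = mech, b = config$b,
               rate = if (mech == "direct") config$s else config$a,
               kA = config$kA, uout = config$uout, b1 = config$b1,
               psiK = config$psiK, gating = gating,
               ca_cond = conductance_params(config$alpha, config$d,
                                            config$lambda),
               k_cond = conductance_params(config$alpha_K, config$d_K,
                                           config$lambda_K),
               cb = cilium_body_params(nu_t = config$vCat,
                                       psi_tr = config$psi_tr,
                                       ut = config$ut),
               tcond = conductance_params(config$alpha_t, config$d_t,
                                          config$lambda_t))
}

#' @rdname as_clamp_params
#' @export
as_coupled_params <- function(config) {
  coupled_params(b = config$b, b1 = config$b1, s = config$s, rho = config$rho,
                 kA = config$kA, uout = config$uout, psiK = config$psiK,
                 nuCast = config$nu_Ca_st, nuKst = config$nu_K_st,
                 vCah = config$vCah, vKca = config$vKca, vCat = config$vCat,
                 psi_tr = config$psi_tr, ut = config$ut,
                 gating = indirect_gating(kC = config$kC, cac0 = config$cac0),
                 ca_cond = conductance_params(config$alpha, config$d,
                                              config$lambda),
                 k_cond = conductance_params(config$alpha_K, config$d_K,
                                             config$lambda_K),
                 h_cond = conductance_params(config$alpha_h, config$d_h,
                                             config$lambda_h),
                 t_cond = conductance_params(config$alpha_t, config$d_t,
                                             config$lambda_t))
}

#' @rdname as_clamp_params
#' @export
as_clamp_protocol <- function(config) {
  clamp_protocol(psi0 = config$psi0, psi1 = config$psi1, tau0 = config$tau0,
                 tauK = config$tauK, duration = config$duration,
                 mechanism = config$mechanism,
                 include_K = isTRUE(config$include_K))
}

#' Run a preset end to end
#'
#' Executes the simulation a preset describes (clamp presets run
#' [simulate_clamp()], free-membrane presets run [simulate_free()]) and
#' returns the trajectory.
#'
#' @param name Preset name or a configuration list.
#' @return A `ciliary_trajectory`.
#' @export
run_preset <- function(name) {
  cfg <- if (is.character(name)) figure_preset(name) else name
  if (identical(cfg$run, "free")) {
    simulate_free(as_coupled_params(cfg), schedule = cfg$I0,
                  duration = cfg$duration, variant = cfg$variant,
                  rtol = cfg$rtol, atol = cfg$atol)
  } else {
    simulate_clamp(as_clamp_protocol(cfg), as_clamp_params(cfg),
                   n_out = cfg$n_out, rtol = cfg$rtol, atol = cfg$atol)
  }
}

fmt12 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 12, format = "g") else as.character(x)
}

#' Write a trajectory (or any table) to CSV with a metadata sidecar
#'
#' The trajectory header is fixed (`eta,u,gate,i_ca,i_k,i_full,psi`), floats
#' are serialised at 12 significant digits, and a `<path>.meta.yaml` sidecar
#' records the run configuration (when available), the package version and
#' an MD5 hash of the configuration text, so outputs are reproducible and
#' attributable. Identical inputs produce byte-identical files.
#'
#' @param traj A `ciliary_trajectory` (for `write_trajectory`) or any
#'   data.frame (for `write_table`).
#' @param path Output CSV path.
#' @param config Optional configuration list recorded in the sidecar.
#' @param sidecar Write the metadata sidecar (default TRUE).
#' @return Invisibly, the output path.
#' @export
write_trajectory <- function(traj, path, config = NULL, sidecar = TRUE) {
  cols <- c("eta", "u", "gate", "i_ca", "i_k", "i_full", "psi")
  missing_cols <- setdiff(cols, names(traj))
  if (length(missing_cols))
    stop("trajectory lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(traj)[, cols, drop = FALSE]
  write_table(df, path, config = config, sidecar = sidecar)
}

#' @rdname write_trajectory
#' @export
write_table <- function(traj, path, config = NULL, sidecar = TRUE) {
  df <- as.data.frame(traj)
  lines <- paste(names(df), collapse = ",")
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, fmt12), sep = ","))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  if (sidecar) {
    cfg_text <- if (is.null(config)) "" else yaml::as.yaml(config)
    meta <- list(
      tool = "ciliadyn",
      version = as.character(utils::packageVersion("ciliadyn")),
      columns = names(df),
      rows = nrow(df),
      config = config,
      config_md5 = config_hash(config)
    )
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' MD5 hash of a configuration
#'
#' Hashes the canonical YAML serialisation of a configuration list; the
#' sidecar written by [write_trajectory()] stores this value so a result
#' file can be matched to the exact configuration that produced it.
#'
#' @param config Configuration list (or NULL).
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(if (is.null(config)) "" else yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Read back a trajectory CSV
#'
#' @param path CSV path written by [write_trajectory()].
#' @return A `ciliary_trajectory` data.frame.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("ciliary_trajectory", "data.frame")
  df
}
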