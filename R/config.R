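#' Run a simulation from a configuration file
#'
#' A flat YAML configuration names the model builder and any overrides:
#'
#' ```yaml
#' model: three_state          # two_state | competition | three_state
#' rates: {gef_conc: 1000, k_gap_off: 0.01, k_gap_cat: 1}
#' gap_level: 1                # two_state only
#' initial: {GAP: 1000, GD: 10}
#' mutant: {gap_cat_factor: 0}
#' effectors:
#'   - {name: cRaf, conc: 50, k_on: 1.0e-4, k_off: 1.0e-3}
#' feedback: {type: allosteric, k_exch_max: 0.005, K_A: 5}
#' t_end: 42000
#' sample_dt: 900
#' ```
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return `read_model_config`: the configuration list;
#'   `build_network_from_config`: a `reaction_network`;
#'   `run_model_config`: a `ras_sim`.
#' @export
read_model_config <- function(config) {
  if (is.character(config)) yaml::read_yaml(config) else config
}

#' @rdname read_model_config
#' @export
build_network_from_config <- function(config) {
  cfg <- read_model_config(config)
  model <- cfg$model %||% "three_state"
  k <- do.call(rate_constants, as.list(cfg$rates))
  net <- switch(model,
    two_state = build_two_state_model(k, gap_level = cfg$gap_level %||% 1),
    competition = build_competition_model(k),
    three_state = build_three_state_model(k),
    stop("unknown model: ", model))
  for (e in cfg$effectors)
    net <- add_effector(net, e$name, e$conc,
                        k_on = e$k_on %||% 1e-4, k_off = e$k_off %||% 1e-3)
  if (!is.null(cfg$mutant))
    net <- apply_mutant(net, do.call(mutant_spec, cfg$mutant))
  if (!is.null(cfg$feedback)) {
    fb <- cfg$feedback
    net <- switch(fb$type,
      recruitment = build_recruitment_feedback_model(
        net, do.call(recruitment_params, fb[setdiff(names(fb), "type")])),
      allosteric = build_allosteric_feedback_model(
        net, do.call(allosteric_params, fb[setdiff(names(fb), "type")])),
      stop("unknown feedback type: ", fb$type))
  }
  net
}

#' @rdname read_model_config
#' @export
run_model_config <- function(config) {
  cfg <- read_model_config(config)
  net <- build_network_from_config(cfg)
  ic <- do.call(initial_state, c(list(net), as.list(cfg$initial)))
  simulate(net, ic,
           t_end = cfg$t_end %||% 42000,
           sample_dt = cfg$sample_dt %||% 900)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
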