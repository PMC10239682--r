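# Workbench: validated run configuration, artifact serialisation, and
# the stage runners behind the command-line interface
# (inst/cli/splitsteal-cli.R).

run_config_defaults <- function() {
  list(
    n_omega = 3L, n_belief = 4L,       # prior grid resolutions
    lambda = 1.0, k = 0.4,
    pots = list(n = 8L, min = 2, max = 207365),
    pi_money = NULL,                   # NULL = planning_config() default
    tau_grid = c(30, 100, 300, 1000),
    fold_size = 5L,
    n_restarts = 50L,
    bootstrap_B = 1000L,
    n_components = 150L,
    seed = 1L,
    synth = list(n_observers = 500L, trials_per_observer = 8L,
                 m_players = 20L, perturb_scale = 1,
                 n_observers_specific = 20L, sparsity = 0.3,
                 noise_sd = 0.1)
  )
}

#' Build and validate a run configuration
#'
#' Unknown keys are rejected; known keys override the defaults.
#'
#' @param ... configuration entries, or a single named list.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  defaults <- run_config_defaults()
  unknown <- setdiff(names(args), names(defaults))
  stop_if(length(unknown) > 0,
          paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, args)
  if (!is.null(args$synth)) {
    unknown_s <- setdiff(names(args$synth), names(defaults$synth))
    stop_if(length(unknown_s) > 0,
            paste("unknown synth config keys:",
                  paste(unknown_s, collapse = ", ")))
  }
  stop_if(cfg$lambda < 0, "lambda must be >= 0")
  stop_if(cfg$k <= 0, "k must be positive")
  stop_if(any(cfg$tau_grid <= 0), "tau_grid must be positive")
  stop_if(cfg$n_omega < 2L || cfg$n_belief < 2L,
          "grid resolutions must be >= 2")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON
#' @param path JSON file path.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a run configuration to JSON
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
dump_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]  # NULLs mean "use the default"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Planning config derived from a run config.
planning_from_run <- function(cfg) {
  pm <- cfg$pi_money
  if (is.null(pm)) planning_config(lambda = cfg$lambda)
  else planning_config(lambda = cfg$lambda, pi_money_values = pm$values,
                       pi_money_probs = pm$probs)
}

run_pots <- function(cfg) {
  if (is.list(cfg$pots))
    pot_grid(cfg$pots$n, c(cfg$pots$min, cfg$pots$max))
  else as.numeric(cfg$pots)
}

#' Serialise a concept transform to JSON
#' @param transform a [concept_transform()].
#' @param path output path.
#' @export
write_transform_json <- function(transform, path) {
  obj <- list(beta = transform$beta, b = transform$b,
              sigma2 = transform$sigma2, k = transform$k,
              tau = transform$tau, basis = transform$basis,
              scale = transform$scale,
              components = rownames(transform$beta),
              emotions = colnames(transform$beta))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a concept transform from JSON
#' @param path JSON path written by [write_transform_json()].
#' @return a [concept_transform()].
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- if (is.null(dim(obj$beta)))
    matrix(as.numeric(obj$beta), nrow = length(obj$components)) else
      obj$beta
  scale <- NULL
  if (!is.null(obj$scale)) {
    scale <- as.numeric(unlist(obj$scale))
    names(scale) <- names(obj$scale) %||% obj$basis
  }
  concept_transform(beta, as.numeric(obj$b), as.numeric(obj$sigma2),
                    k = as.numeric(obj$k),
                    tau = as.numeric(obj$tau %||% NA_real_),
                    basis = obj$basis, scale = scale)
}

#' Simulate choice probabilities per condition
#'
#' Marginal cooperation probability `P(a1 = C)` for each pot under the
#' anonymous and public forward models with a uniform prior.
#'
#' @param cfg a [run_config()].
#' @param out optional directory; writes `choice_probabilities.csv`.
#' @return data.frame `pot, model_variant, p_cooperate`.
#' @export
run_simulate <- function(cfg = run_config(), out = NULL) {
  pcfg <- planning_from_run(cfg)
  pots <- run_pots(cfg)
  gp <- uniform_prior(cfg$n_omega, cfg$n_belief, "generic")
  bp <- uniform_prior(cfg$n_omega, cfg$n_belief, "base")
  rows <- list()
  for (pot in pots) {
    pa <- pcfg; pa$model_variant <- "anonymous"
    pol_a <- action_policy(bp$support, pot, pa)
    repu <- reputation_expectation(bp, pot, pcfg)
    pol_p <- action_policy(gp$support, pot, pcfg, repu = repu)
    rows[[length(rows) + 1L]] <- data.frame(
      pot = pot,
      model_variant = c("anonymous", "public"),
      p_cooperate = c(sum(bp$weights * pol_a[, "C"]),
                      sum(gp$weights * pol_p[, "C"])))
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out, "choice_probabilities.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the full synthetic fit/predict/evaluate pipeline
#'
#' Builds a synthetic world from the config, generates generic training
#' and specific-player test data, selects the Laplace scale by
#' cross-validation, and evaluates held-out predictions and
#' personalization bias. All randomness flows from `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @param out optional output directory for artifacts
#'   (`transform.json`, `evaluation.json`).
#' @param control optimiser controls.
#' @return list with `world`, `cv`, `transform` (fit at the modal
#'   selected tau), `report` (overall ccc, per-emotion ccc, bias
#'   correlations).
#' @export
run_fit_predict_evaluate <- function(cfg = run_config(), out = NULL,
                                     control = fit_control()) {
  pcfg <- planning_from_run(cfg)
  world <- synth_world(seed = cfg$seed, n_omega = cfg$n_omega,
                       n_belief = cfg$n_belief, pots = run_pots(cfg),
                       cfg = pcfg, sparsity = cfg$synth$sparsity,
                       noise_sd = cfg$synth$noise_sd, k = cfg$k,
                       n_components = cfg$n_components)
  gdata <- generate_emotion_dataset(world, cfg$synth$n_observers,
                                    cfg$synth$trials_per_observer,
                                    seed = cfg$seed + 1L)
  players <- generate_specific_players(
    world, cfg$synth$m_players, cfg$synth$perturb_scale,
    n_observers = cfg$synth$n_observers_specific,
    trials_per_observer = cfg$synth$trials_per_observer,
    seed = cfg$seed + 2L)
  sdata <- do.call(rbind, lapply(players, `[[`, "emotion_data"))
  ssamples <- lapply(players, `[[`, "samples")
  cv <- select_tau_cv(gdata, world_samples(world), sdata, ssamples,
                      cfg$tau_grid, fold_size = cfg$fold_size,
                      seed = cfg$seed, control = control)
  tau_hat <- as.character(stats::median(cv$selected_tau))
  transform <- cv$fits[[tau_hat]] %||% cv$fits[[1]]

  pred_all <- c(); emp_all <- c()
  for (p in cv$predictions) {
    common <- intersect(rownames(p$predicted), rownames(p$empirical))
    pred_all <- c(pred_all, as.numeric(p$predicted[common, , drop = FALSE]))
    emp_all <- c(emp_all, as.numeric(p$empirical[common, , drop = FALSE]))
  }
  overall <- lin_ccc(pred_all, emp_all)

  gen_pred <- outcome_expectations(
    predict_condition_expectations(transform, world_samples(world)))
  gen_emp <- outcome_expectations(empirical_condition_means(gdata))
  bias <- t(vapply(names(players), function(p) {
    mdl <- emotion_bias(outcome_expectations(cv$predictions[[p]]$predicted),
                        gen_pred)
    emp <- emotion_bias(outcome_expectations(cv$predictions[[p]]$empirical),
                        gen_emp)
    bias_correlation(mdl, emp)
  }, numeric(3)))

  report <- list(ccc = overall,
                 selected_tau = cv$selected_tau,
                 bias = list(per_player = bias,
                             mean = colMeans(bias)))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_transform_json(transform, file.path(out, "transform.json"))
    jsonlite::write_json(list(ccc = overall,
                              selected_tau = cv$selected_tau,
                              bias_mean = as.list(colMeans(bias)),
                              seed = cfg$seed),
                         file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(world = world, cv = cv, transform = transform, report = report)
}

#' Dispatch a named pipeline stage
#'
#' @param cfg a [run_config()].
#' @param stage one of `"simulate"`, `"synth"`, `"fit"`.
#' @param out optional output directory.
#' @return the stage's return value.
#' @export
run_stage <- function(cfg, stage = c("simulate", "synth", "fit"),
                      out = NULL) {
  stage <- match.arg(stage)
  switch(stage,
         simulate = run_simulate(cfg, out),
         synth = {
           world <- synth_world(seed = cfg$seed, n_omega = cfg$n_omega,
                                n_belief = cfg$n_belief,
                                pots = run_pots(cfg),
                                cfg = planning_from_run(cfg),
                                sparsity = cfg$synth$sparsity,
                                noise_sd = cfg$synth$noise_sd,
                                k = cfg$k,
                                n_components = cfg$n_components)
           d <- generate_emotion_dataset(world, cfg$synth$n_observers,
                                         cfg$synth$trials_per_observer,
                                         seed = cfg$seed + 1L)
           if (!is.null(out)) {
             dir.create(out, showWarnings = FALSE, recursive = TRUE)
             utils::write.csv(d, file.path(out, "emotions_generic.csv"),
                              row.names = FALSE)
           }
           d
         },
         fit = run_fit_predict_evaluate(cfg, out))
}
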