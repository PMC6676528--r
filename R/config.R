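# Structured run configuration: schedules, scenarios and observation-model
# parameters are described in a single YAML file per run.  A JSON schema for
# the format ships in inst/schema/; loading validates the same structural
# rules in R and rejects malformed configs with a named error.

#' Read a run configuration
#'
#' Parses a YAML configuration describing either a single-genome event
#' schedule (`type: schedule`, keys `M1` and `events`) or a speciation
#' scenario (`type: scenario`, keys `M1`, `shared`, `branch_a`,
#' `branch_b`), plus optional `decay` (`C`, `lambda`), `sd_model`
#' (`intercept`, `slope`) and `replicates` entries.  The format is
#' described by the JSON schema shipped at
#' `system.file("schema", "run-config.schema.json", package = "wgdfrac")`;
#' the same structural rules are enforced on load.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `type`, `object` (a [event_schedule()]
#'   or [speciation_scenario()]), `decay`, `sd_model`, `replicates`,
#'   and `raw` (the parsed YAML).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_wgdfrac(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_wgdfrac("config must be a YAML mapping")
  type <- raw$type %||% if (!is.null(raw$events)) "schedule" else "scenario"
  if (!type %in% c("schedule", "scenario"))
    stop_wgdfrac("config `type` must be 'schedule' or 'scenario'")
  M1 <- raw$M1 %||% stop_wgdfrac("config is missing `M1`")

  parse_event <- function(e, allow = c("wgd", "speciation", "observation")) {
    if (!is.list(e) || is.null(e$kind)) stop_wgdfrac("each event needs a `kind`")
    if (!e$kind %in% allow)
      stop_wgdfrac(sprintf("unexpected event kind '%s' here", e$kind))
    if (is.null(e$time)) stop_wgdfrac(sprintf("event of kind '%s' needs a `time`", e$kind))
    e
  }
  obj <- if (type == "schedule") {
    evs <- raw$events %||% stop_wgdfrac("schedule config needs `events`")
    evs <- lapply(evs, parse_event, allow = c("wgd", "observation"))
    kinds <- vapply(evs, `[[`, character(1), "kind")
    if (sum(kinds == "observation") != 1L || kinds[length(kinds)] != "observation")
      stop_wgdfrac("a schedule needs exactly one observation event, last")
    wgds <- lapply(evs[kinds == "wgd"], function(e) {
      r <- e$ploidy %||% (length(e$u) - 1L)
      wgd_event(e$time, survival_dist(r, as.numeric(e$u)))
    })
    event_schedule(M1, wgds, obs_time = evs[[length(evs)]]$time)
  } else {
    shared <- raw$shared %||% stop_wgdfrac("scenario config needs `shared`")
    shared <- lapply(shared, parse_event, allow = c("wgd", "speciation"))
    kinds <- vapply(shared, `[[`, character(1), "kind")
    if (sum(kinds == "speciation") != 1L || kinds[length(kinds)] != "speciation")
      stop_wgdfrac("a scenario's `shared` list needs exactly one speciation event, last")
    sp <- shared[[length(shared)]]
    pre <- lapply(shared[kinds == "wgd"], function(e) {
      r <- e$ploidy %||% (length(e$u) - 1L)
      wgd_event(e$time, survival_dist(r, as.numeric(e$u)))
    })
    parse_branch <- function(b, nm) {
      b <- lapply(b %||% list(list(kind = "observation", time = 0)),
                  parse_event, allow = c("wgd", "observation"))
      kinds <- vapply(b, `[[`, character(1), "kind")
      if (sum(kinds == "observation") != 1L || kinds[length(kinds)] != "observation")
        stop_wgdfrac(sprintf("`%s` needs exactly one observation event, last", nm))
      list(wgds = lapply(b[kinds == "wgd"], function(e) {
        r <- e$ploidy %||% (length(e$u) - 1L)
        wgd_event(e$time, survival_dist(r, as.numeric(e$u)))
      }), obs_time = b[[length(b)]]$time)
    }
    ba <- parse_branch(raw$branch_a, "branch_a")
    bb <- parse_branch(raw$branch_b, "branch_b")
    speciation_scenario(M1, shared = pre,
                        speciation = speciation_event(sp$time,
                                                      as.numeric(sp$u %||% c(0, 0, 1))),
                        branch_a = ba$wgds, branch_b = bb$wgds,
                        obs_time_a = ba$obs_time, obs_time_b = bb$obs_time)
  }
  decay <- if (!is.null(raw$decay))
    decay_model(raw$decay$C %||% 1, raw$decay$lambda %||% 0.09) else decay_model()
  sdm <- if (!is.null(raw$sd_model))
    sd_model(raw$sd_model$intercept %||% 0.12, raw$sd_model$slope %||% -0.1) else sd_model()
  list(type = type, object = obj, decay = decay, sd_model = sdm,
       replicates = raw$replicates %||% 1L, raw = raw)
}

#' @rdname read_run_config
#' @return `read_schedule()` / `read_scenario()` return just the
#'   [event_schedule()] / [speciation_scenario()] and error when the
#'   config is of the other type.
#' @export
read_schedule <- function(path) {
  cfg <- read_run_config(path)
  if (cfg$type != "schedule") stop_wgdfrac("config describes a scenario, not a schedule")
  cfg$object
}

#' @rdname read_run_config
#' @export
read_scenario <- function(path) {
  cfg <- read_run_config(path)
  if (cfg$type != "scenario") stop_wgdfrac("config describes a schedule, not a scenario")
  cfg$object
}

# flatten the effective configuration into `# key: value` header entries
config_header <- function(cfg, extra = character()) {
  obj <- cfg$object
  desc <- if (cfg$type == "schedule") {
    sprintf("M1=%g; %s", obj$M1,
            paste(sprintf("%s@%gMy", obj$events$kind, obj$events$time), collapse = " "))
  } else {
    sprintf("M1=%g; shared %s | A %s | B %s", obj$M1,
            paste(sprintf("%s@%gMy", obj$shared$kind, obj$shared$time), collapse = " "),
            paste(sprintf("%s@%gMy", obj$branch_a$kind, obj$branch_a$time), collapse = " "),
            paste(sprintf("%s@%gMy", obj$branch_b$kind, obj$branch_b$time), collapse = " "))
  }
  c(package = paste0("wgdfrac ", as.character(utils::packageVersion("wgdfrac"))),
    type = cfg$type, model = desc,
    decay = sprintf("C=%g lambda=%g", cfg$decay$C, cfg$decay$lambda),
    sd_model = sprintf("intercept=%g slope=%g", cfg$sd_model$intercept, cfg$sd_model$slope),
    extra)
}
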