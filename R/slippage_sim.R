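#' @title Slipped-strand mispairing simulator
#' @name slippage_sim
#' @description Stochastic simulation of tandem-repeat array evolution at
#'   whole-unit granularity. Per replication, duplication and deletion event
#'   counts are Poisson with the configured rates; each event picks a
#'   uniform position and a geometric block length, a duplication inserting
#'   an adjacent copy of the block and a deletion removing it. When chimera
#'   formation is enabled, a deletion whose 5' breakpoint lies in a Type II
#'   unit and whose 3' breakpoint lies in a downstream Type I unit leaves a
#'   single chimeric Type IV unit in place of the span, the minimal
#'   formalization of repeat-unit loss by misaligned replication.
NULL

#' Simulation configuration
#'
#' @param dup_rate expected duplication events per replication (>= 0;
#'   default 0.05).
#' @param del_rate expected deletion events per replication (>= 0; default
#'   0.02 - duplications outpace deletions, as repeatedly observed for
#'   replication slippage).
#' @param block_p geometric parameter for contiguous block size in units;
#'   block length is 1 + Geom(`block_p`), so `block_p = 1` means single-unit
#'   events. Must lie in (0, 1].
#' @param n_replications number of replication rounds (default 50).
#' @param seed integer seed; every trajectory is a pure function of
#'   (config, initial state).
#' @param chimera_enabled enable Type IV chimera formation on deletion
#'   (default TRUE).
#' @param type_ii,type_i,type_iv unit labels playing the Type II / Type I /
#'   Type IV roles in the chimera rule (defaults 2, 1, 4).
#' @param record_states keep every intermediate state (default TRUE; turn
#'   off for large ensembles).
#' @return a `slippage_config` list.
#' @export
slippage_config <- function(dup_rate = 0.05, del_rate = 0.02,
                            block_p = 0.5, n_replications = 50L,
                            seed = 1L, chimera_enabled = TRUE,
                            type_ii = 2L, type_i = 1L, type_iv = 4L,
                            record_states = TRUE) {
  stopifnot(dup_rate >= 0, del_rate >= 0,
            block_p > 0, block_p <= 1, n_replications >= 0)
  structure(list(dup_rate = dup_rate, del_rate = del_rate,
                 block_p = block_p,
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed),
                 chimera_enabled = isTRUE(chimera_enabled),
                 type_ii = as.integer(type_ii),
                 type_i = as.integer(type_i),
                 type_iv = as.integer(type_iv),
                 record_states = isTRUE(record_states)),
            class = "slippage_config")
}

apply_event <- function(labels, ev, config) {
  pos <- ev$position; len <- ev$block_length
  n <- length(labels)
  if (ev$kind == "dup") {
    block <- labels[pos:(pos + len - 1L)]
    append(labels, block, after = pos + len - 1L)
  } else if (ev$kind == "del") {
    labels[-(pos:(pos + len - 1L))]
  } else {  # chimera: span replaced by one Type IV unit
    c(if (pos > 1L) labels[1:(pos - 1L)] else integer(),
      config$type_iv,
      if (pos + len <= n) labels[(pos + len):n] else integer())
  }
}

#' Simulate tandem-array evolution by replication slippage
#'
#' @param initial integer vector of unit type labels (the initial array),
#'   or an `ArrayState`-like list with `labels`.
#' @param config a [slippage_config()].
#' @return A `slippage_trajectory`: list with `initial`, `states` (when
#'   `record_states`), `final`, `events` (data.frame `generation`, `kind`,
#'   `position`, `block_length`), `extinct`, `config`.
#' @export
simulate_slippage <- function(initial, config) {
  stopifnot(inherits(config, "slippage_config"))
  labels <- as.integer(if (is.list(initial)) initial$labels else initial)
  if (!length(labels)) stop("initial array must be non-empty")
  with_seed_(config$seed, {
    states <- if (config$record_states)
      vector("list", config$n_replications + 1L) else NULL
    if (config$record_states) states[[1L]] <- labels
    events <- list()
    extinct <- FALSE
    gen_reached <- config$n_replications
    for (gen in seq_len(config$n_replications)) {
      n_dup <- rpois(1L, config$dup_rate)
      n_del <- rpois(1L, config$del_rate)
      kinds <- c(rep("dup", n_dup), rep("del", n_del))
      for (kind in kinds) {
        n <- length(labels)
        pos <- sample.int(n, 1L)
        len <- 1L + rgeom(1L, config$block_p)
        len <- min(len, n - pos + 1L)
        ev_kind <- kind
        if (kind == "del") {
          if (len >= n) {  # would empty the array: extinction
            extinct <- TRUE
            gen_reached <- gen - 1L
            break
          }
          if (config$chimera_enabled && len >= 2L &&
              labels[pos] == config$type_ii &&
              labels[pos + len - 1L] == config$type_i)
            ev_kind <- "chimera"
        }
        ev <- list(generation = gen, kind = ev_kind,
                   position = pos, block_length = len)
        labels <- apply_event(labels, ev, config)
        events[[length(events) + 1L]] <- ev
      }
      if (extinct) break
      if (config$record_states) states[[gen + 1L]] <- labels
    }
    if (config$record_states && extinct)
      states <- states[seq_len(gen_reached + 1L)]
    ev_df <- if (length(events)) do.call(rbind, lapply(events, function(e)
      data.frame(generation = e$generation, kind = e$kind,
                 position = e$position, block_length = e$block_length,
                 stringsAsFactors = FALSE)))
    else data.frame(generation = integer(), kind = character(),
                    position = integer(), block_length = integer(),
                    stringsAsFactors = FALSE)
    structure(list(initial = as.integer(
                     if (is.list(initial)) initial$labels else initial),
                   states = states, final = labels,
                   generations = gen_reached,
                   events = ev_df, extinct = extinct, config = config),
              class = "slippage_trajectory")
  })
}

#' @export
print.slippage_trajectory <- function(x, ...) {
  cat(sprintf(
    "slippage_trajectory: %d -> %d units over %d replication(s), %d event(s)%s\n",
    length(x$initial), length(x$final), x$generations, nrow(x$events),
    if (x$extinct) " [EXTINCT]" else ""))
  invisible(x)
}

#' Replay a trajectory's event log from its initial state
#'
#' Deterministically re-applies the recorded events; the result must equal
#' the recorded final state (and every recorded intermediate state), which
#' is the simulator's bookkeeping invariant.
#'
#' @param trajectory a `slippage_trajectory`.
#' @return list with `final` (replayed labels) and `states` (per-generation
#'   states keyed as in the trajectory).
#' @export
replay_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "slippage_trajectory"))
  labels <- trajectory$initial
  cfg <- trajectory$config
  ev <- trajectory$events
  states <- vector("list", trajectory$generations + 1L)
  states[[1L]] <- labels
  for (gen in seq_len(trajectory$generations)) {
    rows <- which(ev$generation == gen)
    for (i in rows)
      labels <- apply_event(labels, as.list(ev[i, ]), cfg)
    states[[gen + 1L]] <- labels
  }
  # events from a truncating (extinction) generation, if any
  extra <- which(ev$generation > trajectory$generations)
  for (i in extra)
    labels <- apply_event(labels, as.list(ev[i, ]), cfg)
  list(final = labels, states = states)
}

#' Summarize an ensemble of slippage trajectories
#'
#' @param trajectories list of `slippage_trajectory` objects (>= 1).
#' @return list with `n`, `final_lengths`, `mean_final_length`,
#'   `sd_final_length`, `type_counts` (matrix: trajectories x types),
#'   `chimera_events`, `extinction_fraction`.
#' @export
summarize_trajectories <- function(trajectories) {
  if (!length(trajectories)) stop("need at least one trajectory")
  stopifnot(all(vapply(trajectories, inherits, TRUE, "slippage_trajectory")))
  finals <- lapply(trajectories, `[[`, "final")
  lens <- lengths(finals)
  all_types <- sort(unique(unlist(finals)))
  tc <- matrix(unlist(lapply(finals, function(f)
    as.integer(table(factor(f, levels = all_types))))),
    ncol = length(all_types), byrow = TRUE,
    dimnames = list(NULL, all_types))
  list(n = length(trajectories),
       final_lengths = lens,
       mean_final_length = mean(lens),
       sd_final_length = sd(lens),
       type_counts = tc,
       chimera_events = vapply(trajectories, function(t)
         sum(t$events$kind == "chimera"), 0L),
       extinction_fraction = mean(vapply(trajectories, `[[`, TRUE, "extinct")))
}

#' Run many independent trajectories with derived seeds
#'
#' Trajectory `i` uses seed `base_seed + i`, so the ensemble is reproducible
#' and each member independent.
#'
#' @param initial initial label vector.
#' @param config a [slippage_config()]; its `seed` is used as `base_seed`.
#' @param n number of trajectories.
#' @return list of `slippage_trajectory`.
#' @export
simulate_ensemble <- function(initial, config, n) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- (config$seed + i) %% .Machine$integer.max
    simulate_slippage(initial, cfg)
  })
}
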