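#' Configuration of the coupled dyad simulator
#'
#' The simulator steps two animals frame by frame through a
#' two-state (moving/freezing) chain with CS-modulated switching hazards and
#' optional social coupling. Per frame, a moving animal starts freezing with
#' hazard `on(t)` and a freezing animal resumes moving with hazard `off(t)`:
#'
#' * pre-CS: `on_pre`, `off_pre` (little freezing, short bouts);
#' * CS, `u` seconds after onset: `on(u) = on_asym + (on_peak - on_asym)
#'   exp(-u / on_decay_s)` and `off_cs` — a high onset hazard that relaxes
#'   toward an asymptote, producing the rapid rise of freezing probability
#'   within ~5 s of CS onset followed by a slow decline.
#'
#' Social coupling acts only while the dyad is incongruent (one freezes, one
#' moves) and is hazard-multiplicative, so `gamma = 0` is exactly neutral:
#'
#' * `gamma_follow` multiplies, by `1 + gamma_follow`, the hazard of the
#'   animal that did **not** break the last congruent state to copy its
#'   partner's new state (the "follow" mechanism);
#' * `gamma_retroact_freeze` / `gamma_retroact_move` multiply, by
#'   `1 + gamma`, the **breaker's** hazard of reversing its own
#'   synchrony-breaking switch within `tau_s` seconds of breaking joint
#'   freezing / joint moving (the "retroact" mechanisms). Because reversal
#'   and partner-follow compete for the same incongruent episodes, the
#'   retroact coupling is flux-preserving: it also multiplies the break
#'   hazard out of the corresponding congruent state by the factor by which
#'   the boosted reversal shortens episodes, keeping the expected number of
#'   partner-follow events constant. A retroacting animal thus makes more
#'   self-corrected exploratory breaks instead of starving its partner of
#'   follow opportunities.
#'
#' Each subject carries a log-normal multiplier on its freeze-onset hazard
#' (individual fear level); `buffering_shift` in `[0, 1]` shrinks the two
#' partners' log-multipliers toward their mean, emulating fear
#' buffering/equalization by the partner's presence.
#'
#' Minimum bout length is enforced by refractory suppression: after entering
#' freezing an animal cannot switch for `min_bout_frames - 1` frames, and
#' freeze onsets too close to the session end to complete a bout are
#' suppressed. This keeps the coupling dynamics intact (no post-hoc bout
#' merging) and guarantees simulated ethograms pass validation.
#'
#' @param layout A [session_layout()].
#' @param on_pre,off_pre Pre-CS onset/offset hazards per frame.
#' @param on_peak,on_asym,on_decay_s CS freeze-onset hazard: initial peak,
#'   asymptote, exponential relaxation time constant (seconds).
#' @param off_cs CS freeze-offset hazard per frame.
#' @param gamma_follow,gamma_retroact_freeze,gamma_retroact_move Coupling
#'   strengths (>= 0; 0 = uncoupled).
#' @param tau_s Retroact memory window in seconds.
#' @param buffering_shift Equalization of partners' freeze-onset multipliers
#'   in `[0, 1]`.
#' @param subject_sd SD of the per-subject log-normal onset multiplier.
#' @param min_bout_frames Minimum freezing-bout length in frames (default 4,
#'   i.e. 1 s at 4 fps).
#' @param max_hazard Upper cap applied to every per-frame hazard.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout = session_layout(),
                       on_pre = 0.010, off_pre = 0.25,
                       on_peak = 0.45, on_asym = 0.030, on_decay_s = 25,
                       off_cs = 0.090,
                       gamma_follow = 0, gamma_retroact_freeze = 0,
                       gamma_retroact_move = 0, tau_s = 2,
                       buffering_shift = 0, subject_sd = 0.25,
                       min_bout_frames = 4L, max_hazard = 0.9) {
  stopifnot(inherits(layout, "session_layout"))
  hz <- c(on_pre, off_pre, on_peak, on_asym, off_cs, max_hazard)
  if (any(hz < 0) || any(hz > 1)) stop("hazards must lie in [0, 1]")
  if (gamma_follow < 0 || gamma_retroact_freeze < 0 || gamma_retroact_move < 0) {
    stop("coupling strengths gamma must be >= 0")
  }
  if (buffering_shift < 0 || buffering_shift > 1) stop("buffering_shift must be in [0, 1]")
  if (tau_s * layout$fps < 1) stop("tau_s must cover at least one frame")
  structure(
    list(layout = layout, on_pre = on_pre, off_pre = off_pre,
         on_peak = on_peak, on_asym = on_asym, on_decay_s = on_decay_s,
         off_cs = off_cs, gamma_follow = gamma_follow,
         gamma_retroact_freeze = gamma_retroact_freeze,
         gamma_retroact_move = gamma_retroact_move,
         tau_frames = as.integer(round(tau_s * layout$fps)),
         buffering_shift = buffering_shift, subject_sd = subject_sd,
         min_bout_frames = as.integer(min_bout_frames),
         max_hazard = max_hazard),
    class = "sim_config"
  )
}

# Per-frame hazard schedules over the whole session (index 1 = frame 0).
hazard_schedule <- function(config) {
  lay <- config$layout
  t_all <- seq_len(lay$n_frames) - 1L
  in_cs <- t_all >= lay$cs_start
  u <- (t_all - lay$cs_start) / lay$fps  # seconds since CS onset
  on <- ifelse(in_cs,
               config$on_asym + (config$on_peak - config$on_asym) * exp(-u / config$on_decay_s),
               config$on_pre)
  off <- ifelse(in_cs, config$off_cs, config$off_pre)
  list(on = on, off = off)
}

# Core frame-stepping engine for one pair. `mult_on` are the two subjects'
# freeze-onset multipliers; `scripted_b` (0/1 full-session trace) replaces
# animal B with a playback pattern that receives no coupling.
simulate_pair_engine <- function(config, mult_on = c(1, 1), scripted_b = NULL,
                                 coupled = TRUE) {
  lay <- config$layout
  n <- lay$n_frames
  sched <- hazard_schedule(config)
  minb <- config$min_bout_frames
  gf <- config$gamma_follow
  grf <- config$gamma_retroact_freeze
  grm <- config$gamma_retroact_move
  tau <- config$tau_frames
  cap <- config$max_hazard

  xa <- integer(n); xb <- integer(n)
  if (!is.null(scripted_b)) {
    stopifnot(length(scripted_b) == n)
    xb <- as.integer(scripted_b)
  }
  sa <- 0L; sb <- if (is.null(scripted_b)) 0L else xb[1L]
  rc_a <- 0L; rc_b <- 0L
  breaker <- 0L; broke_state <- NA_integer_; timer <- 0L
  xa[1L] <- sa; if (is.null(scripted_b)) xb[1L] <- sb

  hazard_for <- function(state, partner_state, mult_self, mult_partner,
                         rc, who, t) {
    h <- if (state == 1L) sched$off[t] else sched$on[t] * mult_self
    if (coupled && state != partner_state) {
      if (breaker == who && timer > 0L) {
        # breaker's reversal boost (retroact mechanism)
        if (!is.na(broke_state) && broke_state == 0L && state == 0L) h <- h * (1 + grf)
        if (!is.na(broke_state) && broke_state == 3L && state == 1L) h <- h * (1 + grm)
      } else if (breaker != who) {
        # non-breaker copies the partner's new state (follow mechanism)
        h <- h * (1 + gf)
      }
    } else if (coupled && state == partner_state) {
      # flux-preserving break boost: with boosted reversal the per-episode
      # follow probability drops by (hp + hb) / (hp + hb (1 + g)); raising
      # the break rate by the inverse factor keeps expected follow events
      # constant while multiplying self-corrected (retroact) episodes.
      if (state == 1L && grf > 0) {
        hb <- sched$on[t] * mult_self          # breaker's re-freeze hazard
        hp <- sched$off[t] * (1 + gf)          # partner's follow hazard
        if (hp + hb > 0) h <- h * (hp + hb * (1 + grf)) / (hp + hb)
      }
      if (state == 0L && grm > 0) {
        hb <- sched$off[t]                     # breaker's re-move hazard
        hp <- sched$on[t] * mult_partner * (1 + gf)
        if (hp + hb > 0) h <- h * (hp + hb * (1 + grm)) / (hp + hb)
      }
    }
    if (rc > 0L) return(0)
    # never start a bout that cannot reach the minimum length
    if (state == 0L && t > n - minb + 1L) return(0)
    min(h, cap)
  }

  for (t in 2:n) {
    ha <- hazard_for(sa, sb, mult_on[1L], mult_on[2L], rc_a, 1L, t)
    sw_a <- stats::runif(1) < ha
    if (is.null(scripted_b)) {
      hb <- hazard_for(sb, sa, mult_on[2L], mult_on[1L], rc_b, 2L, t)
      sw_b <- stats::runif(1) < hb
    } else {
      sw_b <- xb[t] != sb
    }
    pa <- sa; pb <- sb
    if (sw_a) {
      sa <- 1L - sa
      rc_a <- if (sa == 1L) minb - 1L else 0L
    } else rc_a <- max(rc_a - 1L, 0L)
    if (is.null(scripted_b)) {
      if (sw_b) {
        sb <- 1L - sb
        rc_b <- if (sb == 1L) minb - 1L else 0L
      } else rc_b <- max(rc_b - 1L, 0L)
    } else sb <- xb[t]
    xa[t] <- sa
    if (is.null(scripted_b)) xb[t] <- sb

    # breaker bookkeeping on the joint transition
    if (pa == pb && sa != sb) {
      breaker <- if (sw_a) 1L else 2L
      broke_state <- if (pa == 1L) 0L else 3L   # the congruent state just broken
      timer <- tau
    } else if (sa == sb) {
      breaker <- 0L; broke_state <- NA_integer_; timer <- 0L
    } else if (sw_a && sw_b) {
      breaker <- 0L; broke_state <- NA_integer_; timer <- 0L  # 1<->2 double switch
    } else {
      timer <- max(timer - 1L, 0L)
    }
  }
  list(trace_a = xa, trace_b = xb)
}

#' Simulate one dyad of freezing ethograms
#'
#' Runs the coupled two-animal chain described in [sim_config()] over a full
#' session and converts each animal's trace to a validated [ethogram()].
#' `configuration = "SINGLE"` simulates the same two subjects (same
#' individual onset multipliers) with all coupling and buffering switched
#' off, emulating testing in separate chambers.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; randomness is derived from
#'   `derive_seed(seed, dyad_id + configuration)`, so cohorts are
#'   reproducible regardless of simulation order.
#' @param dyad_id Dyad identifier.
#' @param subject_ids Length-2 character vector; default derives from
#'   `dyad_id`.
#' @param sex_composition,familiarity,treatment,group Metadata passed to
#'   [dyad()].
#' @param configuration `"PAIR"` (coupled) or `"SINGLE"` (uncoupled control
#'   of the same subjects).
#' @param subject_effects Optional length-2 numeric of per-subject onset
#'   multipliers; drawn log-normally when NULL. Pass the multipliers
#'   returned in `attr(, "subject_effects")` to re-test the same animals.
#' @return A [dyad()] with attributes `subject_effects` and `config`.
#' @export
simulate_dyad <- function(config = sim_config(), seed = 1L, dyad_id = "d1",
                          subject_ids = paste0(dyad_id, c("a", "b")),
                          sex_composition = "MM", familiarity = "familiar",
                          treatment = "control", group = NULL,
                          configuration = c("PAIR", "SINGLE"),
                          subject_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  configuration <- match.arg(configuration)
  set.seed(derive_seed(seed, paste(dyad_id, configuration)))
  if (is.null(subject_effects)) {
    subject_effects <- exp(stats::rnorm(2L, 0, config$subject_sd))
  }
  mult <- subject_effects
  coupled <- configuration == "PAIR"
  if (coupled && config$buffering_shift > 0) {
    lm <- log(mult)
    lm <- lm + config$buffering_shift * (mean(lm) - lm)
    mult <- exp(lm)
  }
  eng <- simulate_pair_engine(config, mult_on = mult, coupled = coupled)
  eth_a <- ethogram(subject_ids[1L], trace_to_bouts(eng$trace_a), config$layout)
  eth_b <- ethogram(subject_ids[2L], trace_to_bouts(eng$trace_b), config$layout)
  out <- dyad(dyad_id, eth_a, eth_b, sex_composition = sex_composition,
              familiarity = familiarity, treatment = treatment, group = group,
              configuration = configuration)
  attr(out, "subject_effects") <- subject_effects
  attr(out, "config") <- config
  out
}

#' Simulate a cohort of dyads
#'
#' Per-dyad seeds are derived deterministically from the cohort seed and the
#' dyad id. Optional across-dyad heterogeneity in the coupling strengths
#' (uniform over a range) induces the count-versus-synchrony correlations the
#' group statistics are designed to detect.
#'
#' @inheritParams simulate_dyad
#' @param n_dyads Number of dyads (>= 1).
#' @param id_prefix Prefix for dyad ids (`<prefix>01`, ...).
#' @param gamma_follow_range,gamma_retroact_freeze_range,gamma_retroact_move_range
#'   Optional length-2 ranges; when given, each dyad's coupling strength is
#'   drawn uniformly from the range (overriding the value in `config`).
#' @return A list with `dyads` (list of [dyad()]s) and `params` (data frame
#'   of the per-dyad coupling strengths actually used).
#' @export
simulate_cohort <- function(config = sim_config(), n_dyads = 20L, seed = 1L,
                            sex_composition = "MM", familiarity = "familiar",
                            treatment = "control", group = NULL,
                            configuration = "PAIR",
                            id_prefix = NULL,
                            gamma_follow_range = NULL,
                            gamma_retroact_freeze_range = NULL,
                            gamma_retroact_move_range = NULL) {
  stopifnot(n_dyads >= 1L)
  if (is.null(id_prefix)) id_prefix <- tolower(sex_composition)
  ids <- sprintf("%s%02d", id_prefix, seq_len(n_dyads))
  set.seed(derive_seed(seed, paste0("cohort_", id_prefix)))
  draw <- function(range, fallback) {
    if (is.null(range)) rep(fallback, n_dyads) else stats::runif(n_dyads, range[1], range[2])
  }
  gfs <- draw(gamma_follow_range, config$gamma_follow)
  grfs <- draw(gamma_retroact_freeze_range, config$gamma_retroact_freeze)
  grms <- draw(gamma_retroact_move_range, config$gamma_retroact_move)
  dyads <- lapply(seq_len(n_dyads), function(i) {
    cfg_i <- config
    cfg_i$gamma_follow <- gfs[i]
    cfg_i$gamma_retroact_freeze <- grfs[i]
    cfg_i$gamma_retroact_move <- grms[i]
    simulate_dyad(cfg_i, seed = seed, dyad_id = ids[i],
                  sex_composition = sex_composition, familiarity = familiarity,
                  treatment = treatment, group = group,
                  configuration = configuration)
  })
  list(
    dyads = dyads,
    params = data.frame(dyad_id = ids, gamma_follow = gfs,
                        gamma_retroact_freeze = grfs,
                        gamma_retroact_move = grms)
  )
}

#' Simulate a subject paired with a playback partner
#'
#' Emulates the robot-ball control: one dyad member replays a fixed freezing
#' pattern (an existing [ethogram()]) and receives no social input, while
#' the live subject is simulated and may couple to the playback per the
#' coupling strengths in `config` (`gamma = 0` emulates a non-social object;
#' `gamma > 0` a socially salient one).
#'
#' @param pattern An [ethogram()] providing the playback member's trace.
#' @param config A [sim_config()] (its layout must match the pattern's).
#' @inheritParams simulate_dyad
#' @param subject_id Id of the simulated live subject.
#' @return A [dyad()] whose member `a` is the simulated subject and member
#'   `b` the playback pattern (trace identical to `pattern`).
#' @export
playback_partner <- function(pattern, config = sim_config(), seed = 1L,
                             dyad_id = "pb1", subject_id = paste0(dyad_id, "a"),
                             sex_composition = "MM") {
  stopifnot(inherits(pattern, "ethogram"), inherits(config, "sim_config"))
  if (!identical(unclass(pattern$layout), unclass(config$layout))) {
    stop("pattern layout does not match the simulation layout")
  }
  set.seed(derive_seed(seed, paste(dyad_id, "playback")))
  mult <- exp(stats::rnorm(1L, 0, config$subject_sd))
  script <- bouts_to_trace(pattern, c(0L, config$layout$n_frames))
  eng <- simulate_pair_engine(config, mult_on = c(mult, 1), scripted_b = script)
  eth_a <- ethogram(subject_id, trace_to_bouts(eng$trace_a), config$layout)
  out <- dyad(dyad_id, eth_a, pattern, sex_composition = sex_composition,
              treatment = "playback")
  attr(out, "subject_effects") <- mult
  out
}
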