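# Symbolic structure of the rule-selection task: three spatial rules map four
# stimulus corners of a 2x2 matrix onto four response keys. On every trial two
# actions sharing the rule are planned; a retro-cue tests one of them (high
# priority 70%, low 30%), under an adaptive response deadline.

.conjrsa_rules <- c("vertical", "horizontal", "diagonal")
.conjrsa_locations <- c("left-top", "right-top", "left-bottom", "right-bottom")
# numeric-pad geometry: 4 5 over 1 2
.conjrsa_keys <- c("left-top" = 4L, "right-top" = 5L,
                   "left-bottom" = 1L, "right-bottom" = 2L)
.conjrsa_cutoff_steps <- c(11.8, 23.5, 35.3)

#' Task rules and stimulus locations
#'
#' The task uses three action rules (`vertical`, `horizontal`, `diagonal`)
#' that each map the four corner locations of a 2x2 stimulus matrix
#' bijectively onto the four response keys (number pad 4, 5, 1, 2).
#' @return `task_rules()` and `task_locations()` return character vectors;
#'   `location_keys()` the named key map.
#' @export
task_rules <- function() .conjrsa_rules

#' @rdname task_rules
#' @export
task_locations <- function() .conjrsa_locations

#' @rdname task_rules
#' @export
location_keys <- function() .conjrsa_keys

#' Map a stimulus location to its response under a rule
#'
#' The `horizontal` rule reflects left/right (left-top maps to right-top),
#' the `vertical` rule reflects top/bottom, and the `diagonal` rule applies
#' both reflections (point reflection through the centre). Every rule is an
#' involution: applying it twice returns the input location.
#'
#' @param rule one of `"vertical"`, `"horizontal"`, `"diagonal"`.
#' @param stimulus one of the four corner locations, see [task_locations()].
#' @return the response location (character scalar).
#' @examples
#' response_for("horizontal", "left-top")     # "right-top"
#' response_for("diagonal", "right-bottom")   # "left-top"
#' @export
response_for <- function(rule, stimulus) {
  if (length(rule) != 1L || !rule %in% .conjrsa_rules)
    stop_conjrsa(sprintf("unknown rule: %s", paste(rule, collapse = ", ")),
                 "conjrsa_invalid_argument")
  if (length(stimulus) != 1L || !stimulus %in% .conjrsa_locations)
    stop_conjrsa(sprintf("unknown location: %s", paste(stimulus, collapse = ", ")),
                 "conjrsa_invalid_argument")
  parts <- strsplit(stimulus, "-", fixed = TRUE)[[1L]]
  lr <- parts[1L]; tb <- parts[2L]
  flip_lr <- function(x) if (x == "left") "right" else "left"
  flip_tb <- function(x) if (x == "top") "bottom" else "top"
  out <- switch(rule,
    horizontal = paste0(flip_lr(lr), "-", tb),
    vertical   = paste0(lr, "-", flip_tb(tb)),
    diagonal   = paste0(flip_lr(lr), "-", flip_tb(tb)))
  out
}

#' Table of the 12 action constellations
#'
#' An action constellation is one rule x stimulus combination together with
#' its implied response; 3 rules x 4 stimulus locations give 12
#' constellations per action plan. Ids are stable across runs (rules in the
#' order vertical, horizontal, diagonal; locations left-top, right-top,
#' left-bottom, right-bottom).
#'
#' @return a data.frame with columns `id` (1-12), `rule`, `stimulus`,
#'   `response`, `key` (number-pad key of the response).
#' @export
constellation_table <- function() {
  grid <- expand.grid(stimulus = .conjrsa_locations, rule = .conjrsa_rules,
                      stringsAsFactors = FALSE)[, c("rule", "stimulus")]
  grid$id <- seq_len(nrow(grid))
  grid$response <- mapply(response_for, grid$rule, grid$stimulus, USE.NAMES = FALSE)
  grid$key <- unname(.conjrsa_keys[grid$response])
  grid[, c("id", "rule", "stimulus", "response", "key")]
}

# id lookup: constellation id for (rule, stimulus) vectors
constellation_id <- function(rule, stimulus) {
  ri <- match(rule, .conjrsa_rules)
  si <- match(stimulus, .conjrsa_locations)
  if (anyNA(ri) || anyNA(si))
    stop_conjrsa("unknown rule or location", "conjrsa_invalid_argument")
  (ri - 1L) * 4L + si
}

#' Generate a randomized trial design
#'
#' Samples the symbolic content of `n_trials` trials: a shared rule, the two
#' stimulus locations (high- and low-priority plan), which plan is tested
#' (high with probability `p_high`), and whether the two locations overlap
#' (rate `p_overlap`). Overlap trials - where both plans demand the same
#' response - are generated for design fidelity but flagged for exclusion
#' from all analyses.
#'
#' @param n_trials number of trials.
#' @param p_high probability that the high-priority plan is tested (default
#'   0.7, the task's 70/30 priority manipulation).
#' @param p_overlap probability that both plans share the stimulus location
#'   (default 0.25).
#' @param seed integer seed; the same seed reproduces the same table.
#' @param trials_per_block block size used for the per-block colour/priority
#'   assignment label.
#' @return a data.frame (one row per trial) with columns `trial`, `block`,
#'   `rule`, `stim_high`, `stim_low`, `tested` ("high"/"low"), `overlap`,
#'   `color_high` ("green"/"blue" label, no analytic role),
#'   `correct_response_high`, `correct_response_low`, `const_high`,
#'   `const_low` (constellation ids).
#' @export
generate_design <- function(n_trials, p_high = 0.7, p_overlap = 0.25,
                            seed = NULL, trials_per_block = 9L) {
  stopifnot(is_count(n_trials), p_high >= 0, p_high <= 1,
            p_overlap >= 0, p_overlap <= 1)
  with_seed(seed, {
    # balanced shuffled deck of the 12 (rule, stimulus) combinations for the
    # high-priority plan: marginally uniform, near-equal counts per
    # constellation (the task orthogonalizes rules and locations)
    combo <- sample(rep(seq_len(12L), length.out = n_trials))
    rule <- .conjrsa_rules[(combo - 1L) %/% 4L + 1L]
    stim_high <- .conjrsa_locations[(combo - 1L) %% 4L + 1L]
    overlap <- stats::runif(n_trials) < p_overlap
    # low-plan stimulus: equals the high location on overlap trials;
    # otherwise dealt balanced (shuffled) over the three alternative
    # locations within each high-plan combination, keeping the low plan's
    # constellation counts near-uniform as well
    stim_low <- character(n_trials)
    stim_low[overlap] <- stim_high[overlap]
    for (g in unique(combo)) {
      idx <- which(combo == g & !overlap)
      if (!length(idx)) next
      alts <- setdiff(.conjrsa_locations, .conjrsa_locations[(g - 1L) %% 4L + 1L])
      deck <- sample(rep(alts, length.out = length(idx)))
      stim_low[idx] <- deck
    }
    tested <- ifelse(stats::runif(n_trials) < p_high, "high", "low")
    block <- (seq_len(n_trials) - 1L) %/% as.integer(trials_per_block) + 1L
    n_blocks <- max(block)
    col_by_block <- sample(c("green", "blue"), n_blocks, replace = TRUE)
    out <- data.frame(
      trial = seq_len(n_trials),
      block = block,
      rule = rule,
      stim_high = stim_high,
      stim_low = stim_low,
      tested = tested,
      overlap = stim_high == stim_low,
      color_high = col_by_block[block],
      stringsAsFactors = FALSE)
    out$correct_response_high <- mapply(response_for, out$rule, out$stim_high,
                                        USE.NAMES = FALSE)
    out$correct_response_low <- mapply(response_for, out$rule, out$stim_low,
                                       USE.NAMES = FALSE)
    out$const_high <- constellation_id(out$rule, out$stim_high)
    out$const_low <- constellation_id(out$rule, out$stim_low)
    out
  })
}

#' Classify a registered response
#'
#' Scores a response against the trial's tested plan: `correct` if it matches
#' the tested plan's correct response, `swap` if it matches the untested
#' plan's correct response (selecting the wrong prepared action), `other`
#' for any remaining response, and `omission` when no response was
#' registered. Overlap trials (both plans demand the same response) cannot
#' be scored and raise a classed error (`conjrsa_overlap_trial`).
#'
#' @param trial one row of a [generate_design()] table (list or 1-row
#'   data.frame).
#' @param response a location string, or `NA`/`NULL` for no response.
#' @return one of `"correct"`, `"swap"`, `"other"`, `"omission"`.
#' @export
classify_response <- function(trial, response) {
  if (is.data.frame(trial)) trial <- as.list(trial[1L, ])
  if (isTRUE(trial$overlap))
    stop_conjrsa("overlap trial: both plans share the response; flagged for exclusion",
                 "conjrsa_overlap_trial")
  if (is.null(response) || length(response) == 0L || is.na(response))
    return("omission")
  tested_resp <- if (identical(trial$tested, "high"))
    trial$correct_response_high else trial$correct_response_low
  untested_resp <- if (identical(trial$tested, "high"))
    trial$correct_response_low else trial$correct_response_high
  if (identical(response, tested_resp)) "correct"
  else if (identical(response, untested_resp)) "swap"
  else "other"
}

#' Adaptive response-deadline state
#'
#' The cutoff interval starts at 1200 ms. After any incorrect trial it
#' increases by a step drawn uniformly from \{11.8, 23.5, 35.3\} ms and the
#' correct-streak counter resets; after the fifth consecutive correct trial
#' it decreases by such a step and the counter resets; otherwise only the
#' counter advances. The cutoff is floored at 100 ms.
#'
#' @param current starting cutoff in ms.
#' @return a `cutoff_state` list with fields `current` and
#'   `consecutive_correct`.
#' @export
cutoff_state <- function(current = 1200) {
  stopifnot(current > 0)
  structure(list(current = current, consecutive_correct = 0L),
            class = "cutoff_state")
}

#' @rdname cutoff_state
#' @param state a `cutoff_state`.
#' @param correct logical: was the trial correct?
#' @param step optional fixed step in ms; by default drawn from the current
#'   RNG stream.
#' @export
update_cutoff <- function(state, correct, step = NULL) {
  stopifnot(inherits(state, "cutoff_state"))
  draw <- function() step %||% sample(.conjrsa_cutoff_steps, 1L)
  if (!isTRUE(correct)) {
    state$current <- state$current + draw()
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 5L) {
      state$current <- max(100, state$current - draw())
      state$consecutive_correct <- 0L
    }
  }
  state
}
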