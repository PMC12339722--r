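# Memory-performance metrics: object-recall ratio, drop-error normalisation
# by ranking within sampled potential errors, success classification, and
# the first-half versus second-half performance trend.

#' Object-recall performance
#'
#' Ratio of correctly recalled objects to total object recalls within the
#' requested scope.
#'
#' @param behavior Behavior tibble with `kind`, `correct` and `trial`.
#' @param scope "session" (default), "first_half" or "second_half"; odd
#'   trial counts place the middle trial in the first half.
#' @return Proportion correct in [0, 1].
#' @export
object_recall_performance <- function(behavior, scope = "session") {
  obj <- dplyr::filter(behavior, .data$kind == "object")
  if (scope != "session") {
    half <- ceiling(max(behavior$trial) / 2)
    obj <- if (scope == "first_half") {
      dplyr::filter(obj, .data$trial <= half)
    } else {
      dplyr::filter(obj, .data$trial > half)
    }
  }
  if (nrow(obj) == 0) stop("no object recalls in scope", call. = FALSE)
  mean(obj$correct)
}

#' Normalize a location-recall drop error
#'
#' Ranks the observed drop error (Euclidean distance between recalled and
#' true location) within `n_potential` uniformly sampled potential responses
#' over the arena interior: the returned value is the fraction of potential
#' drop errors strictly larger than the observed one. 1 is the best possible
#' response, 0 the worst. Sampling is per true location, so the metric is
#' location-dependent as the ranking implies.
#'
#' @param drop_error Observed drop error, virtual units (>= 0).
#' @param true_location Length-2 (x, y) of the true object location.
#' @param arena Rectangle side lengths c(w, h), or a list
#'   `list(shape = "disc", radius = , center = )`.
#' @param n_potential Monte Carlo sample size (default 1e6).
#' @param seed Integer seed (deterministic ranking).
#' @return Normalized performance in [0, 1].
#' @export
normalize_drop_error <- function(drop_error, true_location, arena = c(100, 100),
                                 n_potential = 1e6, seed = 1) {
  stopifnot(drop_error >= 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  if (is.list(arena) && identical(arena$shape, "disc")) {
    ctr <- arena$center %||% c(0, 0)
    if (sqrt(sum((true_location - ctr)^2)) > arena$radius) {
      stop("true location outside arena", call. = FALSE)
    }
    r <- arena$radius * sqrt(stats::runif(n_potential))
    a <- stats::runif(n_potential, 0, 2 * pi)
    px <- ctr[1] + r * cos(a); py <- ctr[2] + r * sin(a)
  } else {
    if (true_location[1] < 0 || true_location[1] > arena[1] ||
        true_location[2] < 0 || true_location[2] > arena[2]) {
      stop("true location outside arena", call. = FALSE)
    }
    px <- stats::runif(n_potential, 0, arena[1])
    py <- stats::runif(n_potential, 0, arena[2])
  }
  d <- sqrt((px - true_location[1])^2 + (py - true_location[2])^2)
  mean(d > drop_error)
}

#' Classify recall success
#'
#' Object recalls are successful iff correct. Location recalls are
#' successful iff their normalized performance is strictly higher than the
#' session's median normalized performance (the median-valued recall itself
#' is unsuccessful). Flags propagate to the paired encoding segments of the
#' same trial via [label_segments()].
#'
#' @param behavior Behavior tibble (see [gen_session()]).
#' @param arena Arena geometry for [normalize_drop_error()].
#' @param n_potential Monte Carlo sample size per location recall; the
#'   default here is 1e5 for speed (1e6 matches the reference procedure).
#' @param seed Integer seed.
#' @return The behavior tibble with `normalized` and `success` columns.
#' @export
classify_recall_success <- function(behavior, arena = c(100, 100),
                                    n_potential = 1e5, seed = 1) {
  loc <- behavior$kind == "location"
  behavior$normalized <- NA_real_
  if (any(loc)) {
    if (sum(loc) < 2) stop("need >= 2 location recalls for the median", call. = FALSE)
    behavior$normalized[loc] <- purrr::map_dbl(which(loc), function(i) {
      normalize_drop_error(behavior$drop_error[i],
                           c(behavior$true_x[i], behavior$true_y[i]),
                           arena, n_potential, seed + i)
    })
    med <- stats::median(behavior$normalized[loc])
    if (diff(range(behavior$normalized[loc])) < .Machine$double.eps) {
      stop("all normalized values identical; success split undefined",
           call. = FALSE)
    }
    behavior$success <- NA
    behavior$success[loc] <- behavior$normalized[loc] > med
  } else {
    behavior$success <- NA
  }
  behavior$success[!loc] <- behavior$correct[!loc]
  behavior
}

#' Propagate recall success onto segments
#'
#' Encoding segments inherit the success of their trial's recall (an
#' encoding-retrieval pair is successful iff the item or its location was
#' recalled); recall segments carry their own flags.
#'
#' @param segments Segment tibble.
#' @param behavior Output of [classify_recall_success()].
#' @return The segment tibble with a logical `success` column.
#' @export
label_segments <- function(segments, behavior) {
  trial_success <- dplyr::summarise(
    dplyr::group_by(behavior, .data$trial),
    success = any(.data$success, na.rm = TRUE), .groups = "drop")
  seg <- dplyr::left_join(segments, trial_success, by = "trial")
  # recall segments paired to specific events keep the event-level flag
  rec <- segments$type %in% c("recall_object", "recall_location")
  if ("segment_id" %in% names(behavior)) {
    ev <- behavior$success[match(seg$segment_id, behavior$segment_id)]
    seg$success[rec & !is.na(ev)] <- ev[rec & !is.na(ev)]
  }
  seg
}

#' First-half versus second-half performance trend
#'
#' For each session computes the mean performance (object: proportion
#' correct; location: mean normalized value) over the first and second half
#' of trials (odd counts: middle trial to the first half) and runs a
#' two-sided paired t-test across sessions.
#'
#' @param session_behaviors List of behavior tibbles, one per session, each
#'   with `normalized` filled in.
#' @param kind "object" or "location".
#' @return A list: `first`, `second` (per-session means), `t`, `df`, `p`.
#' @export
performance_trend <- function(session_behaviors, kind = c("object", "location")) {
  kind <- match.arg(kind)
  if (length(session_behaviors) < 2) stop("need >= 2 sessions", call. = FALSE)
  halves <- purrr::map_dfr(session_behaviors, function(b) {
    bb <- dplyr::filter(b, .data$kind == !!kind)
    half <- ceiling(max(b$trial) / 2)
    metric <- if (kind == "object") as.numeric(bb$correct) else bb$normalized
    tibble::tibble(first = mean(metric[bb$trial <= half]),
                   second = mean(metric[bb$trial > half]))
  })
  tt <- stats::t.test(halves$first, halves$second, paired = TRUE)
  list(first = halves$first, second = halves$second,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
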