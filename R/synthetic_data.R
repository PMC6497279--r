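# Synthetic camera-sled frame streams. The generator emulates what the
# analysis assumes about real imagery: a 5 frames/s stream in which most
# frames are empty, organisms arrive in patches (overdispersed counts),
# each organism persists in several consecutive frames because successive
# images overlap ~25%, and taxon identity follows a fixed composition.
#
# Arrivals per frame are Gamma-mixed Poisson, i.e. negative binomial with
# mean `organism_rate` and dispersion theta (smaller theta = patchier;
# theta = Inf is the Poisson limit). Overdispersion is not optional
# decoration: at the surveyed arrival rate a pure Poisson stream would
# occupy ~50% of frames, while the survey observed 33%, which is only
# reachable with theta < Inf. `calibrate()` solves theta from the zero
# probability.

#' Configure the synthetic frame-stream generator
#'
#' @param n_frames Number of frames to generate (>= 1).
#' @param composition Named non-negative vector of relative taxon
#'   abundances (need not sum to 1). Default: the packaged camera test-set
#'   composition.
#' @param organism_rate Expected organism arrivals per frame.
#' @param theta Negative-binomial dispersion of per-frame arrivals
#'   (> 0; `Inf` = Poisson).
#' @param persistence_range Integer pair (lo, hi): each organism appears
#'   in `lo`..`hi` consecutive frames, drawn uniformly. Default `c(3, 5)`
#'   for consecutive 5 fps frames; use `c(1, 1)` for records whose frames
#'   are farther apart than any persistence (e.g. every-30th-frame data).
#' @param fps Frame rate, frames per second (default 5); sets `time_s`.
#' @param transect_id Label for the generated transect.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_frames, composition = NULL, organism_rate = 0.1,
                       theta = Inf, persistence_range = c(3, 5), fps = 5,
                       transect_id = "SIM1", seed = 1) {
  if (is.null(composition)) {
    sc <- survey_counts()
    composition <- setNames(sc$test_set, sc$common_name)
    composition <- composition[composition > 0]
  }
  if (any(composition < 0) || all(composition == 0)) {
    stop("composition must be non-negative and not all zero", call. = FALSE)
  }
  if (is.null(names(composition))) {
    stop("composition must be a named vector", call. = FALSE)
  }
  stopifnot(n_frames >= 1, organism_rate >= 0, theta > 0,
            length(persistence_range) == 2,
            persistence_range[1] >= 1, persistence_range[2] <= 30,
            persistence_range[1] <= persistence_range[2])
  structure(list(n_frames = as.integer(n_frames),
                 composition = composition / sum(composition),
                 organism_rate = organism_rate, theta = theta,
                 persistence_range = as.integer(persistence_range),
                 fps = fps, transect_id = transect_id,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic annotated frame stream
#'
#' Per-frame organism arrivals are negative binomial (mean
#' `organism_rate`, dispersion `theta`); each arrival is assigned a taxon
#' by the composition and a persistence drawn uniformly from
#' `persistence_range`, and increments the counts of that many consecutive
#' frames (truncated at the stream end). Identical configs give identical
#' streams.
#'
#' @param config A [sim_config()].
#' @return List with `records` (a `frame_records` tibble) and `truth`
#'   (list: composition proportions, analytic H and N2 of the
#'   composition, and the realized organism table).
#' @export
generate_frame_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_frames
  taxa <- names(config$composition)
  arrivals <- if (is.finite(config$theta)) {
    stats::rnbinom(n, size = config$theta, mu = config$organism_rate)
  } else {
    stats::rpois(n, config$organism_rate)
  }
  total <- sum(arrivals)
  counts <- matrix(0L, nrow = n, ncol = length(taxa),
                   dimnames = list(NULL, taxa))
  organisms <- tibble::tibble(taxon = character(0),
                              first_frame = integer(0),
                              persistence = integer(0))
  if (total > 0) {
    first <- rep.int(seq_len(n), arrivals)
    taxon <- sample(taxa, total, replace = TRUE,
                    prob = config$composition)
    pr <- config$persistence_range
    persist <- if (pr[1] == pr[2]) rep.int(pr[1], total) else
      sample(seq.int(pr[1], pr[2]), total, replace = TRUE)
    organisms <- tibble::tibble(taxon = taxon, first_frame = first,
                                persistence = persist)
    frame_idx <- sequence(persist, from = first)
    taxon_rep <- rep.int(taxon, persist)
    keep <- frame_idx <= n
    tab <- table(factor(frame_idx[keep], levels = seq_len(n)),
                 factor(taxon_rep[keep], levels = taxa))
    counts <- matrix(as.integer(tab), nrow = n,
                     dimnames = list(NULL, taxa))
  }
  records <- frame_records(
    transect_id = config$transect_id,
    frame_index = seq_len(n),
    counts = counts,
    time_s = (seq_len(n) - 1) / config$fps
  )
  p <- config$composition
  truth <- list(
    proportions = p,
    H = -sum(p[p > 0] * log(p[p > 0])),
    N2 = 1 / sum(p^2),
    organisms = organisms
  )
  list(records = records, truth = truth)
}

#' Calibrate arrival rate and patchiness to survey totals
#'
#' Given a total organism count, a frame count, and an occupied-frame
#' fraction, sets `organism_rate = organisms_total / n_frames` and solves
#' the negative-binomial dispersion theta so the zero probability
#' `(theta / (theta + mu))^theta` equals `1 - occupancy`. Applies to
#' records whose frames are far enough apart that each organism is seen
#' at most once (per-frame counts are then iid arrivals).
#'
#' @param organisms_total Total organisms counted (> 0).
#' @param n_frames Frames over which they were counted.
#' @param occupancy Fraction of frames with >= 1 organism, in (0, 1).
#' @param ... Further arguments passed to [sim_config()] (composition,
#'   seed, persistence_range, ...).
#' @return A completed `sim_config` with calibrated rate and theta, and
#'   attribute `"calibration"` recording the solved zero probability.
#' @export
calibrate <- function(organisms_total, n_frames, occupancy, ...) {
  stopifnot(organisms_total > 0, n_frames >= 1)
  if (occupancy <= 0 || occupancy >= 1) {
    stop("occupancy must be in (0, 1)", call. = FALSE)
  }
  mu <- organisms_total / n_frames
  p0_target <- 1 - occupancy
  p0_poisson <- exp(-mu)
  if (abs(p0_target - p0_poisson) < 1e-9) {
    theta <- Inf  # Poisson limit
  } else if (p0_target < p0_poisson) {
    stop("occupancy ", signif(occupancy, 4), " exceeds the Poisson bound 1 - exp(-rate) = ",
         signif(1 - p0_poisson, 4),
         "; a Gamma-mixed (overdispersed) process can only lower occupancy. ",
         "Feasible occupancy at this rate lies in (0, ",
         signif(1 - p0_poisson, 4), "].", call. = FALSE)
  } else {
    # log P(0) = theta * (log theta - log(theta + mu)), monotone in theta
    g <- function(log_theta) {
      th <- exp(log_theta)
      th * (log(th) - log(th + mu)) - log(p0_target)
    }
    root <- stats::uniroot(g, interval = c(-30, 30), tol = 1e-12)
    theta <- exp(root$root)
    if (abs((theta / (theta + mu))^theta - p0_target) > 1e-6) {
      stop("calibration failed to converge", call. = FALSE)
    }
  }
  cfg <- sim_config(n_frames = n_frames, organism_rate = mu, theta = theta,
                    ...)
  attr(cfg, "calibration") <- list(
    p0_target = p0_target,
    p0_achieved = if (is.finite(theta)) (theta / (theta + mu))^theta else exp(-mu),
    poisson_limit = !is.finite(theta)
  )
  cfg
}

#' Generate synthetic beam-trawl catches
#'
#' Per-station multinomial draws from a fixed composition, with an
#' optional "jackpot" multiplier for one (station, taxon) pair emulating a
#' single dominant tow.
#'
#' @param composition Named relative-abundance vector.
#' @param n_stations Number of stations (>= 1); labelled BT1, BT2, ...
#' @param effort Organisms caught per station (integer >= 0; recycled).
#' @param jackpot Optional list with `station` (index or label), `taxon`
#'   and `multiplier`: that station's count of that taxon is multiplied.
#' @param seed Integer seed.
#' @return A `catch_records` tibble.
#' @export
generate_trawl_catches <- function(composition, n_stations, effort,
                                   jackpot = NULL, seed = 1) {
  stopifnot(n_stations >= 1, all(effort >= 0))
  withr::local_seed(seed)
  taxa <- names(composition)
  effort <- rep_len(as.integer(effort), n_stations)
  stations <- paste0("BT", seq_len(n_stations))
  rows <- lapply(seq_len(n_stations), function(i) {
    cnt <- if (effort[i] > 0) {
      as.numeric(stats::rmultinom(1, effort[i], prob = composition))
    } else rep(0, length(taxa))
    tibble::tibble(station_id = stations[i], taxon = taxa, count = cnt,
                   estimated = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(jackpot)) {
    st <- if (is.numeric(jackpot$station)) stations[jackpot$station] else jackpot$station
    hit <- out$station_id == st & out$taxon == jackpot$taxon
    if (!any(hit)) stop("jackpot station/taxon not found", call. = FALSE)
    out$count[hit] <- out$count[hit] * jackpot$multiplier
    out$estimated[hit] <- TRUE
  }
  class(out) <- unique(c("catch_records", class(out)))
  out
}
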