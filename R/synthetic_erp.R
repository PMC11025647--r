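#' Electrode layouts on the unit disk
#'
#' Creates a 2D electrode layout in the package's shared coordinate
#' convention: the closed unit disk, nose up, `x` increasing from left
#' to right, vertex `Cz` at the origin. Either a shipped 32-channel
#' 10-20-like montage (`montage = "montage32"`) or a deterministic
#' layout of `n` electrodes (a square for `n = 4`, otherwise a
#' sunflower spiral) is returned.
#'
#' @param n number of electrodes (at least 4); ignored when `montage`
#'   is given.
#' @param montage optional montage name; currently `"montage32"`.
#' @return an `electrode_layout`: data.frame with columns `label`,
#'   `x`, `y`.
#' @export
make_layout <- function(n = NULL, montage = NULL) {
  if (!is.null(montage)) {
    if (!identical(montage, "montage32")) {
      stop("unknown montage: ", montage, call. = FALSE)
    }
    return(montage32())
  }
  stopifnot(is.numeric(n), n >= 4)
  n <- as.integer(n)
  if (n == 4L) {
    df <- data.frame(label = paste0("E", 1:4),
                     x = c(-0.5, 0.5, -0.5, 0.5),
                     y = c(0.5, 0.5, -0.5, -0.5))
  } else {
    i <- seq_len(n)
    golden <- pi * (3 - sqrt(5))
    r <- 0.9 * sqrt((i - 0.5) / n)
    th <- i * golden
    df <- data.frame(label = sprintf("E%02d", i),
                     x = r * cos(th), y = r * sin(th))
  }
  structure(df, class = c("electrode_layout", "data.frame"))
}

# internal: the shipped 32-channel 10-20-like montage
montage32 <- function() {
  ch <- c("Fp1", -0.28, 0.88,  "Fp2", 0.28, 0.88,
          "AF3", -0.32, 0.72,  "AF4", 0.32, 0.72,
          "F7", -0.75, 0.48,   "F3", -0.42, 0.5,
          "Fz", 0, 0.52,       "F4", 0.42, 0.5,
          "F8", 0.75, 0.48,
          "FC5", -0.62, 0.28,  "FC1", -0.22, 0.27,
          "FC2", 0.22, 0.27,   "FC6", 0.62, 0.28,
          "T7", -0.92, 0,      "C3", -0.45, 0,
          "Cz", 0, 0,          "C4", 0.45, 0,
          "T8", 0.92, 0,
          "CP5", -0.62, -0.28, "CP1", -0.22, -0.27,
          "CP2", 0.22, -0.27,  "CP6", 0.62, -0.28,
          "P7", -0.75, -0.48,  "P3", -0.42, -0.5,
          "Pz", 0, -0.52,      "P4", 0.42, -0.5,
          "P8", 0.75, -0.48,
          "PO3", -0.32, -0.72, "PO4", 0.32, -0.72,
          "O1", -0.28, -0.88,  "Oz", 0, -0.9,
          "O2", 0.28, -0.88)
  m <- matrix(ch, ncol = 3, byrow = TRUE)
  structure(data.frame(label = m[, 1],
                       x = as.numeric(m[, 2]),
                       y = as.numeric(m[, 3]),
                       stringsAsFactors = FALSE),
            class = c("electrode_layout", "data.frame"))
}

#' Smooth spatial fields as sums of Gaussian bumps
#'
#' A `spatial_field` represents a smooth scalp topography as a sum of
#' isotropic Gaussian bumps; it is the generative counterpart of the
#' smooth surfaces later estimated by the tensor-product models.
#'
#' @param centers numeric matrix (or length-2 vector) of bump centers
#'   `(x, y)`.
#' @param widths positive bump widths (SD of the Gaussian, recycled).
#' @param amplitudes bump amplitudes in microvolts (recycled).
#' @return object of class `spatial_field`.
#' @export
spatial_field <- function(centers, widths = 0.5, amplitudes = 1) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2)
  m <- nrow(centers)
  widths <- rep_len(widths, m)
  amplitudes <- rep_len(amplitudes, m)
  if (any(widths <= 0)) stop("widths must be > 0", call. = FALSE)
  structure(list(centers = centers, widths = widths,
                 amplitudes = amplitudes),
            class = "spatial_field")
}

#' Evaluate a spatial field at coordinates
#'
#' @param field a [spatial_field()] or `NULL` (treated as the zero
#'   field).
#' @param x,y coordinate vectors of equal length.
#' @return numeric vector of field values in microvolts.
#' @export
eval_field <- function(field, x, y) {
  if (is.null(field)) return(rep(0, length(x)))
  stopifnot(inherits(field, "spatial_field"))
  out <- rep(0, length(x))
  for (j in seq_len(nrow(field$centers))) {
    d2 <- (x - field$centers[j, 1])^2 + (y - field$centers[j, 2])^2
    out <- out + field$amplitudes[j] * exp(-d2 / (2 * field$widths[j]^2))
  }
  out
}

#' Configuration of the synthetic ERP generator
#'
#' Bundles the generative parameters for single-trial window-mean
#' (300-500 ms) amplitudes: a baseline, a linear trial-number drift, a
#' reanalysis-condition effect topography, a surprisal effect
#' topography (per z-unit), random per-participant and per-stimulus
#' topographies, and Gaussian sensor noise. Negative-going (N400-like)
#' effects are encoded as negative field amplitudes.
#'
#' The defaults place a -1.0 microvolt reanalysis effect over the
#' right-posterior scalp and a -0.8 microvolt-per-z surprisal effect
#' over the centro-posterior scalp, with trial drift 0.5 microvolts per
#' z-unit, noise SD 2 and 12 participants; these are the reference
#' conditions for all recovery experiments in the package.
#'
#' @param baseline grand-mean amplitude, microvolts.
#' @param beta_trial drift per z-unit of trial number.
#' @param field_cond [spatial_field()] for the binary reanalysis
#'   effect.
#' @param field_surp [spatial_field()] for the surprisal effect, per
#'   z-unit.
#' @param sd_participant_field,sd_item_field SDs of random-topography
#'   bump amplitudes.
#' @param sd_noise residual SD, microvolts.
#' @param n_participants number of participants.
#' @param n_trials_per_item presentations of each stimulus per
#'   participant.
#' @param seed integer seed.
#' @return list of class `erp_gen_config`.
#' @export
erp_gen_config <- function(baseline = 2,
                           beta_trial = 0.5,
                           field_cond = spatial_field(c(0.35, -0.45),
                                                      widths = 0.5,
                                                      amplitudes = -1.0),
                           field_surp = spatial_field(c(0, -0.35),
                                                      widths = 0.6,
                                                      amplitudes = -0.8),
                           sd_participant_field = 0.5,
                           sd_item_field = 0.3,
                           sd_noise = 2,
                           n_participants = 12L,
                           n_trials_per_item = 1L,
                           seed = 1L) {
  stopifnot(sd_participant_field >= 0, sd_item_field >= 0, sd_noise >= 0,
            n_participants >= 1, n_trials_per_item >= 1)
  structure(list(baseline = baseline, beta_trial = beta_trial,
                 field_cond = field_cond, field_surp = field_surp,
                 sd_participant_field = sd_participant_field,
                 sd_item_field = sd_item_field, sd_noise = sd_noise,
                 n_participants = as.integer(n_participants),
                 n_trials_per_item = as.integer(n_trials_per_item),
                 seed = as.integer(seed)),
            class = "erp_gen_config")
}

# internal: a random low-rank bump field with amplitudes ~ N(0, sd)
random_bump_field <- function(sd, n_bumps = 3L, width = 0.5) {
  if (sd == 0) return(NULL)
  r <- 0.8 * sqrt(stats::runif(n_bumps))
  th <- stats::runif(n_bumps, 0, 2 * pi)
  spatial_field(cbind(r * cos(th), r * sin(th)), widths = width,
                amplitudes = stats::rnorm(n_bumps, 0, sd))
}

#' Build the generator's stimulus table from surprisal records
#'
#' Reduces a [stimulus_surprisal()] record table (one model) to the
#' per-stimulus table consumed by [generate_erp()]: one row per
#' sentence with a unique `stim_id`, its binary reanalysis coding and
#' its raw critical-word surprisal.
#'
#' @param records data.frame from [stimulus_surprisal()] restricted to
#'   one `model_id`.
#' @return data.frame with columns `stim_id`, `item_id`, `cond`,
#'   `surp`.
#' @export
erp_input_from_records <- function(records) {
  check_columns(records, c("item_id", "cond1", "cond2", "reanalysis",
                           "surprisal_nats"), "records")
  if (length(unique(records$model_id)) > 1L) {
    stop("records must come from a single model_id", call. = FALSE)
  }
  data.frame(stim_id = paste(records$item_id, records$cond1,
                             records$cond2, sep = "."),
             item_id = records$item_id,
             cond = as.integer(records$reanalysis),
             surp = records$surprisal_nats,
             stringsAsFactors = FALSE)
}

#' Generate single-trial window-mean ERP amplitudes
#'
#' Simulates the analysis-ready dependent variable of the topographic
#' models: one window-averaged amplitude per participant x stimulus x
#' electrode (x repetition), composed additively of baseline, trial
#' drift, the condition and surprisal effect fields, random
#' participant and stimulus topographies, and Gaussian noise:
#' `amplitude = baseline + beta_trial * trial_z + field_cond(x, y) * cond +
#' field_surp(x, y) * surp_z + a_p(x, y) + b_s(x, y) + e`.
#' Trial order is randomized independently per participant under the
#' configured seed; continuous predictors are z-scored over the
#' generated dataset. Output is byte-identical under a fixed
#' configuration.
#'
#' @param stimuli data.frame with columns `stim_id`, `cond` (0/1) and
#'   `surp` (raw surprisal, nats), plus optionally `item_id` grouping
#'   sentences into experimental items; see [erp_input_from_records()].
#' @param layout an [make_layout()] electrode layout.
#' @param config an [erp_gen_config()].
#' @param presentation `"all"` presents every stimulus row to every
#'   participant; `"rotate"` presents each item in exactly one of its
#'   condition cells per participant, rotating cells across
#'   participants Latin-square style (requires `item_id`).
#' @return data.frame with one row per participant x presented stimulus
#'   x electrode x repetition: `participant_id`, `stim_id`, `item_id`
#'   (when supplied), `trial_number`, `trial_z`, `electrode`, `x`, `y`,
#'   `cond`, `surp_raw`, `surp_z`, `amplitude`.
#' @export
generate_erp <- function(stimuli, layout, config = erp_gen_config(),
                         presentation = c("all", "rotate")) {
  stopifnot(inherits(layout, "electrode_layout"),
            inherits(config, "erp_gen_config"))
  presentation <- match.arg(presentation)
  check_columns(stimuli, c("stim_id", "cond", "surp"), "stimuli")
  if (any(!is.finite(stimuli$surp))) {
    stop("missing or non-finite surprisal for some stimuli", call. = FALSE)
  }
  if (presentation == "rotate") check_columns(stimuli, "item_id", "stimuli")
  has_item <- "item_id" %in% names(stimuli)
  item_of_stim <- if (has_item) stimuli$item_id else stimuli$stim_id
  items <- unique(item_of_stim)
  n_stim <- nrow(stimuli)
  n_el <- nrow(layout)
  reps <- config$n_trials_per_item
  with_seed(config$seed, {
    part_fields <- lapply(seq_len(config$n_participants), function(p) {
      random_bump_field(config$sd_participant_field)
    })
    item_fields <- lapply(seq_along(items), function(s) {
      random_bump_field(config$sd_item_field)
    })
    f_cond_el <- eval_field(config$field_cond, layout$x, layout$y)
    f_surp_el <- eval_field(config$field_surp, layout$x, layout$y)
    a_p <- vapply(part_fields, eval_field, numeric(n_el),
                  x = layout$x, y = layout$y)    # n_el x n_participants
    b_i <- vapply(item_fields, eval_field, numeric(n_el),
                  x = layout$x, y = layout$y)    # n_el x n_items
    blocks <- vector("list", config$n_participants)
    for (p in seq_len(config$n_participants)) {
      shown <- if (presentation == "all") seq_len(n_stim) else {
        # one cell per item, rotated across participants
        unlist(lapply(seq_along(items), function(ii) {
          cells <- which(item_of_stim == items[ii])
          cells[((ii + p) %% length(cells)) + 1L]
        }))
      }
      order_idx <- sample(rep(shown, reps))
      n_trials <- length(order_idx)
      blocks[[p]] <- data.frame(
        participant_id = sprintf("p%02d", p),
        stim_idx = rep(order_idx, each = n_el),
        trial_number = rep(seq_len(n_trials), each = n_el),
        el_idx = rep(seq_len(n_el), times = n_trials),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, blocks)
    out$stim_id <- stimuli$stim_id[out$stim_idx]
    if (has_item) out$item_id <- stimuli$item_id[out$stim_idx]
    out$electrode <- layout$label[out$el_idx]
    out$x <- layout$x[out$el_idx]
    out$y <- layout$y[out$el_idx]
    out$cond <- stimuli$cond[out$stim_idx]
    out$surp_raw <- stimuli$surp[out$stim_idx]
    out$trial_z <- zscore(out$trial_number)
    out$surp_z <- zscore(out$surp_raw)
    pidx <- as.integer(factor(out$participant_id))
    iidx <- match(item_of_stim[out$stim_idx], items)
    mu <- config$baseline + config$beta_trial * out$trial_z +
      f_cond_el[out$el_idx] * out$cond +
      f_surp_el[out$el_idx] * out$surp_z +
      a_p[cbind(out$el_idx, pidx)] + b_i[cbind(out$el_idx, iidx)]
    out$amplitude <- mu + stats::rnorm(nrow(out), 0, config$sd_noise)
    out$stim_idx <- NULL
    out$el_idx <- NULL
    rownames(out) <- NULL
    out
  })
}

#' Write and read trial-amplitude tables
#'
#' Long-format CSV, one row per participant x stimulus x electrode; the
#' generator configuration (scalar fields and seed) is echoed into a
#' sidecar JSON when `config` is supplied.
#'
#' @param data trial-amplitude data.frame from [generate_erp()].
#' @param path CSV path.
#' @param config optional `erp_gen_config` echoed to `<path>.json`.
#' @return the path, invisibly.
#' @export
write_trials <- function(data, path, config = NULL) {
  utils::write.csv(data, path, row.names = FALSE)
  if (!is.null(config)) {
    meta <- list(baseline = config$baseline, beta_trial = config$beta_trial,
                 sd_participant_field = config$sd_participant_field,
                 sd_item_field = config$sd_item_field,
                 sd_noise = config$sd_noise,
                 n_participants = config$n_participants,
                 n_trials_per_item = config$n_trials_per_item,
                 seed = config$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
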