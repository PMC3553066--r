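#' Configuration of the synthetic expression generator
#'
#' Describes a log2-scale expression matrix with a normal group, a tumour
#' group split into subtypes, and four planted feature classes:
#'
#' * `outlier_up` / `outlier_down` — features shifted by `+/- outlier_delta`
#'   in a small random subset of tumour samples (the regime the outlier
#'   pipeline targets: transcripts extreme in only a few cancer samples);
#'   a fraction of them is confined to a single subtype;
#' * `de` — features shifted by `de_delta` in *all* tumour samples
#'   (classical differential expression; half up, half down);
#' * `noise` — features with inflated variance (`noise_sd *
#'   noise_sd_multiplier`) but no group structure, the natural prey of
#'   variance-based selection;
#' * `background` — everything else.
#'
#' The number of affected samples of an outlier feature is
#' `max(1, round(outlier_sample_fraction * n_tumour))`; for
#' subtype-specific features those samples are drawn from the assigned
#' subtype (capped at its size). Normal samples are pure background. Class
#' membership, directions and subtype assignment are deterministic in the
#' feature index; baselines, noise and affected-sample draws come from
#' per-feature substreams of the master seed, so enlarging the matrix does
#' not perturb existing features.
#'
#' @param n_features,n_normal,n_tumour matrix dimensions (defaults 2000,
#'   10, 20).
#' @param subtype_sizes tumour subtype sizes, summing to `n_tumour`
#'   (default `c(10, 10)`).
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 intensity (defaults 8 and 1.5, typical of normalised arrays).
#' @param noise_sd within-feature measurement noise SD (default 0.5).
#' @param n_outlier_features number of planted outlier features
#'   (default 100).
#' @param outlier_delta planted shift in log2 units (default 4).
#' @param outlier_sample_fraction fraction of tumour samples affected
#'   (default 0.1).
#' @param outlier_direction_mix fraction of outlier features shifted up
#'   (default 0.5).
#' @param subtype_specific_fraction fraction of outlier features confined
#'   to one subtype (default 0.5).
#' @param n_de_features,de_delta differentially expressed features and their
#'   shift (defaults 100 and 1).
#' @param n_noise_features,noise_sd_multiplier high-variance uninformative
#'   features and their SD inflation (defaults 100 and 4).
#' @param seed master seed (default 1).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 2000, n_normal = 10, n_tumour = 20,
                              subtype_sizes = c(10, 10),
                              baseline_mean = 8, baseline_sd = 1.5,
                              noise_sd = 0.5,
                              n_outlier_features = 100, outlier_delta = 4,
                              outlier_sample_fraction = 0.1,
                              outlier_direction_mix = 0.5,
                              subtype_specific_fraction = 0.5,
                              n_de_features = 100, de_delta = 1,
                              n_noise_features = 100, noise_sd_multiplier = 4,
                              seed = 1) {
  cfg <- list(n_features = as.integer(n_features),
              n_normal = as.integer(n_normal),
              n_tumour = as.integer(n_tumour),
              subtype_sizes = as.integer(subtype_sizes),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd,
              n_outlier_features = as.integer(n_outlier_features),
              outlier_delta = outlier_delta,
              outlier_sample_fraction = outlier_sample_fraction,
              outlier_direction_mix = outlier_direction_mix,
              subtype_specific_fraction = subtype_specific_fraction,
              n_de_features = as.integer(n_de_features), de_delta = de_delta,
              n_noise_features = as.integer(n_noise_features),
              noise_sd_multiplier = noise_sd_multiplier,
              seed = as.integer(seed))
  with(cfg, {
    if (n_features < 1L || n_normal < 1L || n_tumour < 2L)
      stop("counts must be positive (and n_tumour >= 2)")
    if (sum(subtype_sizes) != n_tumour)
      stop("'subtype_sizes' must sum to 'n_tumour'")
    if (any(subtype_sizes < 1L)) stop("subtype sizes must be positive")
    if (outlier_sample_fraction <= 0 || outlier_sample_fraction > 1)
      stop("'outlier_sample_fraction' must be in (0, 1]")
    if (outlier_direction_mix < 0 || outlier_direction_mix > 1)
      stop("'outlier_direction_mix' must be in [0, 1]")
    if (subtype_specific_fraction < 0 || subtype_specific_fraction > 1)
      stop("'subtype_specific_fraction' must be in [0, 1]")
    if (noise_sd <= 0 || baseline_sd < 0) stop("SDs must be positive")
    if (n_outlier_features + n_de_features + n_noise_features > n_features)
      stop("planted feature classes exceed 'n_features'")
  })
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' See [simulation_config()] for the generative model. Fully reproducible:
#' the same configuration (including its seed) always yields the same
#' matrix and truth table.
#'
#' @param config a [simulation_config()] object.
#' @return list with `matrix` (a [expression_matrix()] object; samples
#'   `N01.., T01..`) and `truth` (data frame with `feature_id`, `class` in
#'   background/outlier_up/outlier_down/de/noise, `affected_samples`
#'   (comma-joined), `subtype`, `baseline`). The tumour-sample subtype map
#'   is attached to `truth` as attribute `"subtype_map"`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  # leave the caller's RNG stream untouched
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old_seed, envir = globalenv()))
  n_samples <- cfg$n_normal + cfg$n_tumour
  sample_ids <- c(sprintf("N%02d", seq_len(cfg$n_normal)),
                  sprintf("T%02d", seq_len(cfg$n_tumour)))
  tumour_ids <- sample_ids[-seq_len(cfg$n_normal)]
  subtype_of <- rep(sprintf("S%d", seq_along(cfg$subtype_sizes)), cfg$subtype_sizes)
  names(subtype_of) <- tumour_ids

  n_out <- cfg$n_outlier_features
  classes <- rep("background", cfg$n_features)
  classes[seq_len(n_out)] <- "outlier"
  if (cfg$n_de_features > 0L)
    classes[n_out + seq_len(cfg$n_de_features)] <- "de"
  if (cfg$n_noise_features > 0L)
    classes[n_out + cfg$n_de_features + seq_len(cfg$n_noise_features)] <- "noise"

  n_up <- round(cfg$outlier_direction_mix * n_out)
  n_up_specific <- round(cfg$subtype_specific_fraction * n_up)
  n_down_specific <- round(cfg$subtype_specific_fraction * (n_out - n_up))
  m_affected <- max(1L, as.integer(round(cfg$outlier_sample_fraction * cfg$n_tumour)))

  values <- matrix(NA_real_, cfg$n_features, n_samples,
                   dimnames = list(sprintf("F%05d", seq_len(cfg$n_features)),
                                   sample_ids))
  truth <- data.frame(feature_id = rownames(values), class = classes,
                      affected_samples = "", subtype = NA_character_,
                      baseline = NA_real_, stringsAsFactors = FALSE)

  for (f in seq_len(cfg$n_features)) {
    set.seed((cfg$seed + f) %% 2147483647L)
    baseline <- stats::rnorm(1L, cfg$baseline_mean, cfg$baseline_sd)
    sd_f <- if (classes[f] == "noise") cfg$noise_sd * cfg$noise_sd_multiplier else cfg$noise_sd
    row <- stats::rnorm(n_samples, baseline, sd_f)
    truth$baseline[f] <- baseline

    if (classes[f] == "outlier") {
      up <- f <= n_up
      truth$class[f] <- if (up) "outlier_up" else "outlier_down"
      # within each direction, the leading subtype_specific_fraction of
      # features is confined to one subtype, assigned round-robin
      specific <- if (up) f <= n_up_specific else (f - n_up) <= n_down_specific
      if (specific && length(cfg$subtype_sizes) > 0L) {
        st <- sprintf("S%d", ((f - 1L) %% length(cfg$subtype_sizes)) + 1L)
        pool <- tumour_ids[subtype_of == st]
        truth$subtype[f] <- st
      } else {
        pool <- tumour_ids
      }
      m_f <- min(m_affected, length(pool))
      affected <- sort(sample(pool, m_f))
      row[match(affected, sample_ids)] <- row[match(affected, sample_ids)] +
        (if (up) cfg$outlier_delta else -cfg$outlier_delta)
      truth$affected_samples[f] <- paste(affected, collapse = ",")
    } else if (classes[f] == "de") {
      # half shifted up, half down, across all tumour samples
      de_idx <- f - n_out
      dir <- if (de_idx <= ceiling(cfg$n_de_features / 2)) 1 else -1
      row[-seq_len(cfg$n_normal)] <- row[-seq_len(cfg$n_normal)] + dir * cfg$de_delta
      truth$affected_samples[f] <- paste(tumour_ids, collapse = ",")
    }
    values[f, ] <- row
  }

  attr(truth, "subtype_map") <- subtype_of
  list(matrix = expression_matrix(values, cfg$n_normal), truth = truth)
}

#' Precision and recall of outlier recovery against planted truth
#'
#' Scores the up/down outlier tables of a run against a generator truth
#' table, at two levels: feature level (is a planted outlier feature
#' retained in the right direction?) and call level (are the planted
#' (feature, sample) pairs the ones listed?). When nothing was called,
#' precision is reported as 1 by convention (no false positives were made)
#' and recall as 0 if anything was planted.
#'
#' @param truth truth table from [generate_expression()].
#' @param up,down retained-feature tables (e.g. from [run_mcopa()]).
#' @return data frame with columns `direction`, `level`, `precision`,
#'   `recall`, `n_true`, `n_called`.
#' @export
score_recovery <- function(truth, up, down) {
  one <- function(direction, tab) {
    cls <- paste0("outlier_", direction)
    true_feats <- truth$feature_id[truth$class == cls]
    called_feats <- tab$feature_id
    pr <- function(called, true) {
      tp <- length(intersect(called, true))
      c(precision = if (length(called) == 0L) 1 else tp / length(called),
        recall = if (length(true) == 0L) 1 else tp / length(true))
    }
    f <- pr(called_feats, true_feats)
    pair_key <- function(feats, samples_list)
      unlist(mapply(function(fid, s) if (length(s)) paste(fid, s) else character(0),
                    feats, samples_list, SIMPLIFY = FALSE), use.names = FALSE)
    true_pairs <- pair_key(true_feats,
                           lapply(truth$affected_samples[truth$class == cls], split_ids))
    called_pairs <- pair_key(called_feats, lapply(tab$outlier_sample_ids, split_ids))
    p <- pr(called_pairs, true_pairs)
    data.frame(direction = direction,
               level = c("feature", "call"),
               precision = c(f["precision"], p["precision"]),
               recall = c(f["recall"], p["recall"]),
               n_true = c(length(true_feats), length(true_pairs)),
               n_called = c(length(called_feats), length(called_pairs)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(one("up", up), one("down", down))
}
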