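#' Perturbation settings for the local-patch sensitivity test
#'
#' @param patch_length patch length n in sampling points (1 <= n <= T).
#' @param num_perturbations number of random perturbations (>= 2; the
#'   correlation is undefined below that).
#' @param fill_value amplitude the patch is set to (microvolts).
#' @param seed RNG seed for the random (channel, start) draws.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(patch_length, num_perturbations = 100L,
                              fill_value = 0, seed = 1L) {
  stopifnot(patch_length >= 1, num_perturbations >= 2)
  structure(list(patch_length = as.integer(patch_length),
                 num_perturbations = as.integer(num_perturbations),
                 fill_value = as.numeric(fill_value),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Patch length for a given fraction of the sample length
#'
#' The sensitivity test sweeps patch fractions 0.1-0.5 of the sample length;
#' the patch length is the floor of fraction times T (so a 254-point sample
#' yields patches of 25-127 points).
#'
#' @param fraction fraction of the sample length in (0, 1].
#' @param n_timepoints sample length T.
#' @return integer patch length.
#' @export
patch_length <- function(fraction, n_timepoints) {
  stopifnot(fraction > 0, fraction <= 1, n_timepoints >= 1)
  max(1L, as.integer(floor(fraction * n_timepoints)))
}

#' Zero out one local patch in one channel
#'
#' @param sample an [eeg_sample] or matrix.
#' @param channel 1-based channel index.
#' @param start 1-based start index of the patch.
#' @param spec a [perturbation_spec()] (supplies patch length and fill
#'   value).
#' @return the perturbed sample, same type as the input.
#' @export
perturb_patch <- function(sample, channel, start, spec) {
  x <- .as_matrix_sample(sample)
  n <- spec$patch_length
  if (channel < 1 || channel > nrow(x) || start < 1 || start + n - 1 > ncol(x)) {
    stop("input error: patch out of range", call. = FALSE)
  }
  x[channel, start:(start + n - 1L)] <- spec$fill_value
  if (inherits(sample, "eeg_sample")) { sample$values <- x; sample } else x
}

#' Local-patch sensitivity test of a contribution map
#'
#' Randomly perturbs the sample `num_perturbations` times, each time zeroing
#' a single patch of fixed length in one randomly chosen channel at a random
#' position, and correlates the drop in the pre-softmax activation of the
#' target class with the summed contribution inside the patch. A Pearson
#' correlation near 1 means the map tracks local model behaviour faithfully.
#'
#' @param model an `eeg_model` (statistics frozen).
#' @param sample the sample the map was computed for.
#' @param cmap its [contribution_map] (for the predicted class).
#' @param spec a [perturbation_spec()].
#' @return a `sensitivity_result` with fields `patch_fraction`, `pcc`,
#'   `records` (one row per perturbation: channel, start, delta_score,
#'   contribution) and `undefined` (TRUE when either vector has zero
#'   variance).
#' @export
sensitivity_test <- function(model, sample, cmap, spec) {
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  stopifnot(inherits(cmap, "contribution_map"),
            all(dim(cmap$scores) == dim(x)))
  n <- spec$patch_length
  N <- nrow(x); T <- ncol(x)
  if (n > T) stop("input error: patch longer than sample", call. = FALSE)
  old <- .seed_push(spec$seed)
  on.exit(.seed_pop(old), add = TRUE)
  chans <- sample.int(N, spec$num_perturbations, replace = TRUE)
  starts <- sample.int(T - n + 1L, spec$num_perturbations, replace = TRUE)
  s0 <- .forward1(model, x)$scores[cmap$target_class]
  delta <- numeric(spec$num_perturbations)
  contrib <- numeric(spec$num_perturbations)
  for (k in seq_len(spec$num_perturbations)) {
    xp <- x
    span <- starts[k]:(starts[k] + n - 1L)
    xp[chans[k], span] <- spec$fill_value
    delta[k] <- s0 - .forward1(model, xp)$scores[cmap$target_class]
    contrib[k] <- sum(cmap$scores[chans[k], span])
  }
  undefined <- stats::sd(delta) == 0 || stats::sd(contrib) == 0
  pcc <- if (undefined) NA_real_ else stats::cor(delta, contrib)
  structure(list(patch_fraction = n / T, patch_length = n, pcc = pcc,
                 undefined = undefined,
                 records = data.frame(channel = chans, start = starts,
                                      delta_score = delta,
                                      contribution = contrib)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> patch fraction ", round(x$patch_fraction, 3),
      " (", x$patch_length, " points): r = ",
      if (x$undefined) "undefined (zero variance)" else format(x$pcc, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Channel-level sensitivity test
#'
#' Perturbs each channel once (zeroing it entirely) and correlates the
#' per-channel activation drops with the channel contribution map.
#'
#' @param model an `eeg_model`.
#' @param sample the sample.
#' @param chmap its [channel_contribution_map].
#' @param fill_value replacement amplitude.
#' @return a `sensitivity_result` (with `low_power = TRUE` when the model
#'   has fewer than 3 channels, where a correlation is unreliable).
#' @export
sensitivity_test_channels <- function(model, sample, chmap, fill_value = 0) {
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  stopifnot(inherits(chmap, "channel_contribution_map"),
            length(chmap$scores) == nrow(x))
  N <- nrow(x)
  s0 <- .forward1(model, x)$scores[chmap$target_class]
  delta <- vapply(seq_len(N), function(i) {
    xp <- x; xp[i, ] <- fill_value
    s0 - .forward1(model, xp)$scores[chmap$target_class]
  }, numeric(1))
  undefined <- stats::sd(delta) == 0 || stats::sd(chmap$scores) == 0
  pcc <- if (undefined) NA_real_ else stats::cor(delta, chmap$scores)
  structure(list(patch_fraction = NA_real_, patch_length = NA_integer_,
                 pcc = pcc, undefined = undefined, low_power = N < 3L,
                 records = data.frame(channel = seq_len(N), start = 1L,
                                      delta_score = delta,
                                      contribution = chmap$scores)),
            class = "sensitivity_result")
}

# Deterministic small integer derived from a sample's content, used to seed
# per-sample randomness independently of list position.
.content_key <- function(x) {
  as.integer(floor(abs(sum(x * seq_along(x))) %% 1e6))
}

# Linear indices of all points ranked by score descending, ties broken by
# channel index then time index ascending (reproducible deletion order).
.rank_points <- function(scores) {
  N <- nrow(scores)
  idx <- seq_along(scores)
  ch <- ((idx - 1L) %% N) + 1L
  tt <- ((idx - 1L) %/% N) + 1L
  idx[order(-as.vector(scores), ch, tt)]
}

#' Deletion test: probability curve under cumulative removal
#'
#' Ranks sampling points (or channels) by their contribution score in
#' descending order and, for an increasing grid of fractions, zeroes the
#' top-ranked portion and records the model's softmax probability of the
#' originally predicted class. A sharp drop — equivalently a small area under
#' the curve — indicates that the map localizes the features the model
#' actually relies on.
#'
#' @param model an `eeg_model`.
#' @param sample the sample.
#' @param cmap a [contribution_map] (mode `"sample"`) or
#'   [channel_contribution_map] (mode `"channel"`).
#' @param fractions increasing grid in (0, 1]; defaults to 0.01..1 step 0.01
#'   (sample mode) or 1/N..1 step 1/N (channel mode).
#' @param mode `"sample"` or `"channel"`.
#' @param fill_value replacement amplitude for deleted points.
#' @return a `deletion_curve` with fields `fractions`, `probabilities` and
#'   `auc` (trapezoidal area over the recorded grid).
#' @export
deletion_curve <- function(model, sample, cmap, fractions = NULL,
                           mode = c("sample", "channel"), fill_value = 0) {
  mode <- match.arg(mode)
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  N <- nrow(x); T <- ncol(x)
  if (is.null(fractions)) {
    fractions <- if (mode == "sample") seq(0.01, 1, by = 0.01) else seq_len(N) / N
  }
  if (length(fractions) == 0L) stop("input error: empty fraction grid", call. = FALSE)
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1)) {
    stop("input error: fractions must be strictly increasing within (0, 1]",
         call. = FALSE)
  }
  cls <- cmap$target_class
  if (mode == "sample") {
    stopifnot(inherits(cmap, "contribution_map"), all(dim(cmap$scores) == dim(x)))
    ord <- .rank_points(cmap$scores)
    np <- length(ord)
    probs <- vapply(fractions, function(fr) {
      k <- round(fr * np)
      xp <- x
      if (k > 0) xp[ord[seq_len(k)]] <- fill_value
      .softmax(.forward1(model, xp)$scores)[cls]
    }, numeric(1))
  } else {
    sc <- if (inherits(cmap, "channel_contribution_map")) cmap$scores
          else rowMeans(cmap$scores)
    stopifnot(length(sc) == N)
    ord <- order(-sc, seq_len(N))
    probs <- vapply(fractions, function(fr) {
      k <- round(fr * N)
      xp <- x
      if (k > 0) xp[ord[seq_len(k)], ] <- fill_value
      .softmax(.forward1(model, xp)$scores)[cls]
    }, numeric(1))
  }
  auc <- if (length(fractions) > 1) {
    sum(diff(fractions) * (utils::head(probs, -1) + utils::tail(probs, -1)) / 2)
  } else 0
  structure(list(fractions = fractions, probabilities = probs, auc = auc,
                 mode = mode, target_class = cls),
            class = "deletion_curve")
}

#' @export
print.deletion_curve <- function(x, ...) {
  cat("<deletion_curve> ", x$mode, " mode, ", length(x$fractions),
      " fractions, AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Probability after removing a set of channels in one shot
#'
#' One-at-a-time companion of the cumulative channel deletion curve, used by
#' the sample-wise report ("removing the listed channels changes the
#' probability to ...").
#'
#' @param model an `eeg_model`.
#' @param sample the sample.
#' @param channels integer channel indices to zero (may be empty).
#' @param target_class class whose probability is reported.
#' @param fill_value replacement amplitude.
#' @return probability of `target_class` after the removal.
#' @export
channel_removal_probability <- function(model, sample, channels, target_class,
                                        fill_value = 0) {
  x <- .as_matrix_sample(sample)
  .check_shape(model, x)
  if (length(channels) > 0) x[channels, ] <- fill_value
  .softmax(.forward1(model, x)$scores)[target_class]
}

#' Random contribution map baseline
#'
#' I.i.d. uniform(-1, 1) scores, seeded; the reference any faithful
#' attribution method must beat in both tests.
#'
#' @param n_channels,n_timepoints map dimensions.
#' @param seed RNG seed.
#' @param target_class class index stamped on the map.
#' @return a [contribution_map] with method tag `"random"`.
#' @export
random_contribution_map <- function(n_channels, n_timepoints, seed = 1L,
                                    target_class = 1L) {
  old <- .seed_push(seed)
  on.exit(.seed_pop(old), add = TRUE)
  contribution_map(matrix(stats::runif(n_channels * n_timepoints, -1, 1),
                          n_channels, n_timepoints),
                   target_class, "random", "baseline")
}

#' Benchmark attribution methods over a batch of samples
#'
#' Classifies each sample, computes its contribution map for the predicted
#' class with every requested method (plus the random baseline), and runs
#' the requested faithfulness tests. Perturbation draws are paired across
#' methods (same seed per sample and fraction), so methods are compared on
#' identical perturbations.
#'
#' @param model an `eeg_model` (statistics frozen).
#' @param samples list of samples.
#' @param methods attribution method names (see [attribution_config()]).
#' @param tests subset of `c("sensitivity", "deletion")`.
#' @param patch_fractions patch-length fractions for the sensitivity test.
#' @param deletion_fractions fraction grid for the deletion test.
#' @param num_perturbations perturbations per sensitivity configuration.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param include_random include the random-map baseline.
#' @return a `benchmark_result`: `details` (long-format data frame with one
#'   row per sample x method x test x fraction) and `summary`
#'   (median/quartiles per method x test x fraction).
#' @export
benchmark <- function(model, samples, methods = .GROUP1_METHODS,
                      tests = c("sensitivity", "deletion"),
                      patch_fractions = seq(0.1, 0.5, by = 0.1),
                      deletion_fractions = seq(0.01, 0.5, by = 0.01),
                      num_perturbations = 100L, seed = 1L,
                      include_random = TRUE) {
  bad <- setdiff(methods, .ALL_METHODS)
  if (length(bad)) stop("configuration error: unknown method(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(tests, c("sensitivity", "deletion"))
  if (length(bad)) stop("configuration error: unknown test(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  all_methods <- c(methods, if (include_random) "random")
  rows <- list()
  for (si in seq_along(samples)) {
    x <- .as_matrix_sample(samples[[si]])
    cls <- predict_class(model, x)
    key <- .content_key(x)        # seeds follow content, not list position
    maps <- lapply(all_methods, function(m) {
      if (m == "random") {
        random_contribution_map(nrow(x), ncol(x),
                                seed = .derive_seed(seed, key),
                                target_class = cls)
      } else {
        compute_contribution(model, x, cls, attribution_config(m))
      }
    })
    names(maps) <- all_methods
    for (m in all_methods) {
      if ("sensitivity" %in% tests) {
        for (fi in seq_along(patch_fractions)) {
          fr <- patch_fractions[fi]
          spec <- perturbation_spec(patch_length(fr, ncol(x)),
                                    num_perturbations = num_perturbations,
                                    seed = .derive_seed(seed, key * 100 + fi))
          res <- sensitivity_test(model, x, maps[[m]], spec)
          rows[[length(rows) + 1L]] <-
            data.frame(sample = si, method = m, test = "sensitivity",
                       fraction = fr, statistic = res$pcc)
        }
      }
      if ("deletion" %in% tests) {
        dc <- deletion_curve(model, x, maps[[m]], fractions = deletion_fractions)
        rows[[length(rows) + 1L]] <-
          data.frame(sample = si, method = m, test = "deletion",
                     fraction = NA_real_, statistic = dc$auc)
      }
    }
  }
  details <- do.call(rbind, rows)
  key <- paste(details$method, details$test,
               ifelse(is.na(details$fraction), "all", details$fraction))
  summary <- do.call(rbind, lapply(split(details, key), function(d) {
    q <- stats::quantile(d$statistic, c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    data.frame(method = d$method[1], test = d$test[1], fraction = d$fraction[1],
               q1 = q[1], median = q[2], q3 = q[3], n = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(details = details, summary = summary, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", length(unique(x$details$sample)), " samples, ",
      length(unique(x$details$method)), " methods\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Evaluation-batch bookkeeping helpers
#'
#' Small arithmetic utilities for planning evaluation batches:
#' `trial_count()` totals a blocked recording schedule (the sum over blocks
#' of the product of each block's factors, e.g. sessions x tasks x letters);
#' `evaluation_set_size()` is the subjects x classes x per-class-quota
#' product; `quota_selection()` applies a per-class quota per subject,
#' filling any class deficit from the remaining classes, and returns the
#' per-subject selection counts.
#'
#' @param blocks list of integer vectors; each block contributes the product
#'   of its entries.
#' @return `trial_count()`: total number of trials.
#' @examples
#' trial_count(list(c(4, 12, 5), c(1, 20, 5)))  # 340
#' evaluation_set_size(9, 4, 25)                # 900
#' @export
trial_count <- function(blocks) {
  sum(vapply(blocks, prod, numeric(1)))
}

#' @rdname trial_count
#' @param n_subjects,n_classes,per_class factors of the evaluation batch.
#' @export
evaluation_set_size <- function(n_subjects, n_classes, per_class) {
  n_subjects * n_classes * per_class
}

#' @rdname trial_count
#' @param available matrix of available sample counts, subjects in rows,
#'   classes in columns.
#' @param quota per-class quota per subject.
#' @export
quota_selection <- function(available, quota) {
  available <- as.matrix(available)
  target <- quota * ncol(available)
  vapply(seq_len(nrow(available)), function(i) {
    avail <- available[i, ]
    taken <- pmin(avail, quota)
    deficit <- target - sum(taken)
    spare <- avail - taken
    extra <- min(deficit, sum(spare))
    as.numeric(sum(taken) + extra)
  }, numeric(1))
}
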