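#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end pipeline:
#' preprocess (median filter) -> segment (SOA multilevel Otsu, lesion
#' mask) -> extract/fuse/select features -> optional DHO tuning of the
#' classifier hyperparameters on a validation split -> fuzzy-SVM
#' one-vs-rest training -> evaluation on the held-out test split.
#'
#' @param synth a [synthetic_config()]; used when no dataset is passed to
#'   [run_pipeline()].
#' @param window median-filter window.
#' @param k threshold count for segmentation (default 2: background /
#'   tissue / hyperdense lesion).
#' @param segment_params [soa_params()] for the per-image Otsu search.
#' @param use_mask if `TRUE` (default) feature extraction consumes the
#'   masked image (intensities kept inside the lesion mask, zero outside);
#'   if `FALSE`, the full preprocessed image.
#' @param caps_cfg,bottleneck_cfg encoder configurations.
#' @param select_keep,select_bins entropy selection: columns kept and
#'   discretization bins.
#' @param tune if `TRUE`, tune `C` and `gamma` with DHO on a validation
#'   split carved from the training part.
#' @param tune_space named list of `c(low, high)` bounds on `log10(C)` and
#'   `log10(gamma)`.
#' @param tune_params [dho_params()] for the tuning run.
#' @param C,gamma classifier settings used when `tune = FALSE` (and as the
#'   fallback); `gamma = NULL` uses the variance heuristic.
#' @param kernel,scheme,sigma passed to [fsvm_multiclass()].
#' @param train_fraction stratified train share (default 0.7).
#' @param seed global pipeline seed (splits and tuning).
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(synth = synthetic_config(scale = 0.5),
                            window = 3L,
                            k = 2L,
                            segment_params = soa_params(population = 15L, iterations = 40L),
                            use_mask = TRUE,
                            caps_cfg = caps_config(),
                            bottleneck_cfg = bottleneck_config(),
                            select_keep = 250L,
                            select_bins = 16L,
                            tune = TRUE,
                            tune_space = list(log10C = c(-1, 3), log10gamma = c(-5, 1)),
                            tune_params = dho_params(population = 5L, iterations = 8L),
                            C = 10, gamma = NULL,
                            kernel = "rbf", scheme = "centroid-linear", sigma = 0.05,
                            train_fraction = 0.7,
                            seed = 0L) {
  list(
    synth = synth, window = window, k = k, segment_params = segment_params,
    use_mask = use_mask, caps_cfg = caps_cfg, bottleneck_cfg = bottleneck_cfg,
    select_keep = select_keep, select_bins = select_bins,
    tune = tune, tune_space = tune_space, tune_params = tune_params,
    C = C, gamma = gamma, kernel = kernel, scheme = scheme, sigma = sigma,
    train_fraction = train_fraction, seed = as.integer(seed)
  )
}

#' Tune classifier hyperparameters with deer hunting optimization
#'
#' Maximizes validation accuracy over a box of hyperparameters. Dimensions
#' whose bounds coincide are held fixed (a space collapsed to a single
#' point is evaluated once and returned).
#'
#' @param x_train,y_train,x_val,y_val feature matrices and labels of the
#'   training and validation splits (validation must be nonempty).
#' @param space named list of `c(low, high)` bounds; recognised names are
#'   `log10C` and `log10gamma`.
#' @param params a [dho_params()].
#' @param kernel,scheme,sigma passed to [fsvm_multiclass()].
#' @return A list with `C`, `gamma`, `accuracy` (validation), and
#'   `optimizer` (the `swarm_opt` trace, `NULL` for a collapsed space).
#' @export
tune_hyperparameters <- function(x_train, y_train, x_val, y_val,
                                 space = list(log10C = c(-1, 3), log10gamma = c(-5, 1)),
                                 params = dho_params(population = 5L, iterations = 8L),
                                 kernel = "rbf", scheme = "centroid-linear", sigma = 0.05) {
  if (length(y_val) == 0L) stop("validation split is empty", call. = FALSE)
  lv <- levels(factor(y_train))
  fit_acc <- function(C, gamma) {
    m <- fsvm_multiclass(x_train, y_train, C = C, gamma = gamma, kernel = kernel,
                         scheme = scheme, sigma = sigma, levels = lv)
    mean(predict(m, x_val)$label == as.character(y_val))
  }
  lo <- vapply(space, `[`, numeric(1), 1L)
  hi <- vapply(space, `[`, numeric(1), 2L)
  free <- which(hi > lo)
  decode <- function(pos) {
    v <- lo
    v[free] <- pos
    list(C = 10^v[["log10C"]], gamma = 10^v[["log10gamma"]])
  }
  if (length(free) == 0L) {
    hp <- decode(numeric(0))
    return(list(C = hp$C, gamma = hp$gamma,
                accuracy = fit_acc(hp$C, hp$gamma), optimizer = NULL))
  }
  obj <- function(pos) {
    hp <- decode(pos)
    fit_acc(hp$C, hp$gamma)
  }
  res <- dho_optimize(obj, lower = lo[free], upper = hi[free],
                      params = params, sense = "maximize")
  hp <- decode(res$best_position)
  list(C = hp$C, gamma = hp$gamma, accuracy = res$best_fitness, optimizer = res)
}

stratified_split <- function(labels, fraction) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * fraction))
    n_tr <- min(n_tr, length(idx) - 1L) # keep at least one test sample
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Run the end-to-end haemorrhage classification pipeline
#'
#' Executes every stage in order on a synthetic (or supplied) dataset and
#' evaluates on a stratified held-out split. All randomness derives from
#' `cfg$seed`, so two runs with the same config are identical.
#'
#' @param cfg a [pipeline_config()].
#' @param data optional dataset tibble in the schema of
#'   [generate_ich_dataset()] (columns `label` and `image`); generated
#'   from `cfg$synth` when `NULL`.
#' @param stages character subset of
#'   `c("preprocess", "segment", "features", "classify")`; later stages
#'   require the earlier ones, so this acts as a prefix gate (e.g.
#'   `c("preprocess", "segment")` stops after segmentation).
#' @param progress print stage progress.
#' @return An object of class `ich_run_report`: confusion matrix, metric
#'   tibbles, chosen hyperparameters, optimizer histories, per-stage
#'   timings, and the fully resolved config. Gated runs return the
#'   artifacts of the completed stages only.
#' @export
run_pipeline <- function(cfg = pipeline_config(), data = NULL,
                         stages = c("preprocess", "segment", "features", "classify"),
                         progress = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (progress) message(sprintf(...))

  if (is.null(data)) {
    say("generating synthetic dataset (%d slices)", sum(cfg$synth$counts))
    data <- generate_ich_dataset(cfg$synth)
  }
  n <- nrow(data)
  timings$data <- proc.time()[["elapsed"]] - t0

  say("preprocessing %d slices", n)
  tic <- proc.time()[["elapsed"]]
  filtered <- lapply(data$image, median_filter_bisection, window = cfg$window)
  timings$preprocess <- proc.time()[["elapsed"]] - tic
  report <- list(config = cfg, n = n, filtered = NULL, timings = timings)
  if (!"segment" %in% stages) {
    report$filtered <- filtered
    report$timings <- timings
    return(structure(report, class = "ich_run_report"))
  }

  say("segmenting (SOA Otsu, k = %d)", cfg$k)
  tic <- proc.time()[["elapsed"]]
  seg_seeds <- cfg$seed + seq_len(n)
  masks <- vector("list", n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    p <- cfg$segment_params
    p$seed <- seg_seeds[i]
    seg <- otsu_soa(filtered[[i]], k = cfg$k, params = p)
    masks[[i]] <- lesion_mask(apply_thresholds(filtered[[i]], seg$thresholds))
    scores[i] <- seg$score
  }
  timings$segment <- proc.time()[["elapsed"]] - tic
  report$masks <- masks
  report$timings <- timings
  if (!"features" %in% stages) return(structure(report, class = "ich_run_report"))

  say("extracting fused features")
  tic <- proc.time()[["elapsed"]]
  inputs <- lapply(seq_len(n), function(i) {
    img <- unclass(filtered[[i]])
    if (cfg$use_mask) img[!masks[[i]]] <- 0L
    gray_image(img, levels = gray_levels(filtered[[i]]))
  })
  feats <- extract_fused_features(inputs, cfg$caps_cfg, cfg$bottleneck_cfg,
                                  progress = progress)
  keep <- entropy_select(feats, keep = min(cfg$select_keep, ncol(feats)),
                         bins = cfg$select_bins)
  x <- feats[, keep, drop = FALSE]
  timings$features <- proc.time()[["elapsed"]] - tic
  report$selected <- keep
  report$timings <- timings
  if (!"classify" %in% stages) return(structure(report, class = "ich_run_report"))

  say("training fuzzy SVM")
  tic <- proc.time()[["elapsed"]]
  labels <- as.character(data$label)
  lv <- levels(data$label) %||% unique(labels)
  hp <- list(C = cfg$C, gamma = cfg$gamma %||% default_gamma(x), tuned = FALSE)
  tune_opt <- NULL
  split <- with_opt_seed(cfg$seed, {
    train <- stratified_split(labels, cfg$train_fraction)
    val <- integer(0)
    if (cfg$tune) {
      # carve a validation subset out of the training part, stratified
      val <- with(list(), {
        v <- integer(0)
        for (cl in unique(labels[train])) {
          idx <- train[labels[train] == cl]
          if (length(idx) >= 4L) v <- c(v, sample(idx, max(1L, round(length(idx) * 0.25))))
        }
        v
      })
    }
    list(train = train, val = val)
  })
  train <- split$train
  test <- setdiff(seq_len(n), train)
  if (cfg$tune && length(split$val) > 0L) {
    inner <- setdiff(train, split$val)
    tp <- cfg$tune_params
    tp$seed <- cfg$seed + 1000L
    tuned <- tune_hyperparameters(
      x[inner, , drop = FALSE], labels[inner],
      x[split$val, , drop = FALSE], labels[split$val],
      space = cfg$tune_space, params = tp,
      kernel = cfg$kernel, scheme = cfg$scheme, sigma = cfg$sigma
    )
    hp <- list(C = tuned$C, gamma = tuned$gamma, tuned = TRUE,
               val_accuracy = tuned$accuracy)
    tune_opt <- tuned$optimizer
  }
  model <- fsvm_multiclass(
    x[train, , drop = FALSE], labels[train],
    C = hp$C, gamma = hp$gamma, kernel = cfg$kernel,
    scheme = cfg$scheme, sigma = cfg$sigma, levels = lv
  )
  pred <- predict(model, x[test, , drop = FALSE])
  cm <- confusion(labels[test], pred$label, classes = lv)
  metrics <- per_class_metrics(cm)
  timings$classify <- proc.time()[["elapsed"]] - tic
  timings$total <- proc.time()[["elapsed"]] - t0

  structure(
    c(report[c("config", "n")], list(
      split = list(train = train, test = test, validation = split$val),
      hyperparameters = hp,
      tuning = tune_opt,
      model = model,
      confusion = cm,
      metrics = metrics,
      macro = macro_average(metrics),
      segmentation_scores = scores,
      selected = keep,
      timings = timings
    )),
    class = "ich_run_report"
  )
}

#' @export
print.ich_run_report <- function(x, ...) {
  cat(sprintf("<ich_run_report> %d slices\n", x$n))
  if (!is.null(x$macro)) {
    cat(sprintf(
      "  held-out macro: sensitivity %.4f, specificity %.4f, precision %.4f, accuracy %.4f\n",
      x$macro$sensitivity, x$macro$specificity, x$macro$precision, x$macro$accuracy
    ))
    cat(sprintf("  hyperparameters: C = %.3g, gamma = %.3g%s\n",
                x$hyperparameters$C, x$hyperparameters$gamma,
                if (isTRUE(x$hyperparameters$tuned)) " (DHO-tuned)" else ""))
  } else {
    cat("  partial run (stage-gated); no classification artifacts\n")
  }
  invisible(x)
}

#' Per-class metrics of a pipeline run
#'
#' @param x an `ich_run_report`.
#' @param ... unused.
#' @return The per-class metric tibble.
#' @export
tidy.ich_run_report <- function(x, ...) {
  if (is.null(x$metrics)) stop("run has no classification stage", call. = FALSE)
  x$metrics
}

#' @rdname tidy.ich_run_report
#' @export
glance.ich_run_report <- function(x, ...) {
  if (is.null(x$macro)) stop("run has no classification stage", call. = FALSE)
  dplyr::bind_cols(
    tibble::tibble(n = x$n, n_test = length(x$split$test)),
    x$macro
  )
}

#' Metric bar chart of a pipeline run
#'
#' @param object an `ich_run_report`.
#' @param ... unused.
#' @return A ggplot of the four per-class metrics.
#' @export
autoplot.ich_run_report <- function(object, ...) {
  m <- tidy.ich_run_report(object)
  long <- tidyr_pivot(m)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

# small local pivot to avoid a tidyr dependency for one call
tidyr_pivot <- function(m) {
  cols <- c("sensitivity", "specificity", "precision", "accuracy")
  dplyr::bind_rows(lapply(cols, function(cn) {
    tibble::tibble(class = m$class, metric = cn, value = m[[cn]])
  }))
}
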