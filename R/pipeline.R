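#' One-call changing-weight hybrid classification
#'
#' The full classifier on a cube: run the filter feature selection
#' ([run_selection()]), build the weighted hybrid kernel from the selected
#' pair and fit hybrid-kernel K-means ([hkmeans()]).
#'
#' @param cube A [hyper_cube()].
#' @param k Number of clusters.
#' @param max_iter,change_threshold,seed,n_init Passed to [hkmeans()].
#' @param sd_type CV convention; see [coefficient_of_variation()].
#' @param ... Passed to [hkmeans()] and [dissimilarity_matrix()].
#' @return List with `selection` (a `measure_selection`), `kernel` and
#'   `fit` (an `hkmeans`).
#' @export
hcw_ssc <- function(cube, k, max_iter = 100L, change_threshold = 0,
                    seed = 1L, n_init = 1L,
                    sd_type = c("population", "sample"), ...) {
  selection <- run_selection(cube, sd_type = match.arg(sd_type))
  kernel <- as_kernel_spec(selection)
  fit <- hkmeans(cube, k, kernel, max_iter = max_iter,
                 change_threshold = change_threshold, seed = seed,
                 n_init = n_init, ...)
  list(selection = selection, kernel = kernel, fit = fit)
}

#' Run configuration for the pipeline
#'
#' Builds a validated configuration for [run_pipeline()]. Flat key-value
#' config files (one `key = value` per line, `#` comments) can seed the
#' values; explicit arguments override file entries. Change thresholds may
#' be given as fractions (`0.02`) or percentages (`"2%"`).
#'
#' @param mode One of `"simulate"`, `"select"`, `"cluster"`, `"hcwssc"`,
#'   `"elbow"`, `"triplets"`, `"evaluate"`.
#' @param input Input raster (or triplet library for `"triplets"`).
#' @param truth Optional truth class raster for evaluation.
#' @param k Cluster count.
#' @param max_iter Iteration cap.
#' @param change_threshold Relabelling fraction below which iteration stops.
#' @param measures Kernel measures for `"cluster"` mode (1 or 2 ids).
#' @param weights Kernel weights matching `measures`.
#' @param seed RNG seed.
#' @param out Output raster path.
#' @param report Output report (JSON) path.
#' @param config_file Optional flat key-value file.
#' @param ... Extra entries (e.g. scene-simulation parameters `rows`,
#'   `cols`, `n_bands`, `n_classes`, `brightness_noise_sd`,
#'   `additive_noise_sd`).
#' @param verbose Log stages to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(mode, input = NULL, truth = NULL, k = 5,
                       max_iter = 100, change_threshold = 0,
                       measures = NULL, weights = NULL, seed = 1,
                       out = NULL, report = NULL, config_file = NULL,
                       verbose = TRUE, ...) {
  cfg <- list(...)
  if (!is.null(config_file)) {
    file_cfg <- read_flat_config(config_file)
    cfg <- modifyList(file_cfg, cfg)
  }
  supplied <- list(mode = mode, input = input, truth = truth, k = k,
                   max_iter = max_iter, change_threshold = change_threshold,
                   measures = measures, weights = weights, seed = seed,
                   out = out, report = report, verbose = verbose)
  cfg <- modifyList(cfg, supplied[!vapply(supplied, is.null, logical(1))])
  cfg$mode <- match.arg(cfg$mode, c("simulate", "select", "cluster",
                                    "hcwssc", "elbow", "triplets",
                                    "evaluate"))
  cfg$change_threshold <- parse_threshold(cfg$change_threshold)
  cfg$k <- as.integer(cfg$k); cfg$max_iter <- as.integer(cfg$max_iter)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$mode == "evaluate" && (is.null(cfg$input) || is.null(cfg$truth))) {
    stop("evaluate mode needs both a classified raster and a truth raster")
  }
  if (cfg$mode %in% c("select", "cluster", "hcwssc", "elbow", "triplets") &&
      is.null(cfg$input)) {
    stop(cfg$mode, " mode needs an input")
  }
  structure(cfg, class = "run_config")
}

parse_threshold <- function(x) {
  if (is.character(x)) {
    pct <- grepl("%\\s*$", x)
    x <- as.numeric(sub("%\\s*$", "", x))
    if (pct) x <- x / 100
  }
  if (is.na(x) || x < 0 || x >= 1) stop("change threshold must be in [0, 1)")
  x
}

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (line in lines) {
    key <- trimws(sub("=.*", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[hcwssc] ", ...)
}

#' Run the classification pipeline
#'
#' Executes one pipeline mode from a [run_config()]:
#'
#' * `simulate` — generate a synthetic scene, write the cube and its truth
#'   raster;
#' * `select` — feature selection only, write the selection report;
#' * `cluster` — K-means with an explicit kernel (`measures`/`weights`);
#' * `hcwssc` — selection, weighted hybrid fit, optional evaluation;
#' * `elbow` — cluster-count diagnostics, report with the curve;
#' * `triplets` — run a triplet library through the protocol;
#' * `evaluate` — score an existing classification raster against truth.
#'
#' Every stage is logged with its seed and parameters; outputs are entirely
#' reproducible from the configuration.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of the artifacts produced (varies by mode).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_stage(cfg, "mode=", cfg$mode, " seed=", cfg$seed)
  switch(
    cfg$mode,
    simulate = {
      scene <- make_scene(
        rows = as.integer(cfg$rows %||% 64),
        cols = as.integer(cfg$cols %||% 64),
        n_bands = as.integer(cfg$n_bands %||% 30),
        n_classes = as.integer(cfg$n_classes %||% 5),
        brightness_noise_sd = cfg$brightness_noise_sd %||% 0.15,
        additive_noise_sd = cfg$additive_noise_sd %||% 0.01,
        seed = cfg$seed)
      if (!is.null(cfg$out)) write_cube(scene$cube, cfg$out)
      if (!is.null(cfg$truth)) write_class_raster(scene$truth, cfg$truth)
      log_stage(cfg, "scene written: ", cfg$out %||% "<memory>")
      invisible(scene)
    },
    select = {
      cube <- read_cube(cfg$input)
      sel <- run_selection(cube)
      log_stage(cfg, "selected pair: ", paste(sel$pair, collapse = "+"),
                " weights=", paste(signif(sel$weights, 4), collapse = ","))
      if (!is.null(cfg$report)) write_selection_report(sel, cfg$report)
      invisible(sel)
    },
    cluster = {
      cube <- read_cube(cfg$input)
      measures <- strsplit(cfg$measures %||% "ED", ",")[[1]]
      weights <- if (is.null(cfg$weights)) {
        rep(1, length(measures))
      } else if (is.character(cfg$weights)) {
        as.numeric(strsplit(cfg$weights, ",")[[1]])
      } else {
        cfg$weights
      }
      kernel <- kernel_spec(measures, weights)
      fit <- hkmeans(cube, cfg$k, kernel, max_iter = cfg$max_iter,
                     change_threshold = cfg$change_threshold,
                     seed = cfg$seed)
      log_stage(cfg, "fit: ", fit$iterations, " iterations, inertia ",
                signif(fit$inertia, 6))
      finish_fit(cfg, cube, fit, selection = NULL)
    },
    hcwssc = {
      cube <- read_cube(cfg$input)
      res <- hcw_ssc(cube, cfg$k, max_iter = cfg$max_iter,
                     change_threshold = cfg$change_threshold,
                     seed = cfg$seed)
      log_stage(cfg, "selected pair: ",
                paste(res$selection$pair, collapse = "+"),
                " norm weights=",
                paste(signif(res$selection$norm_weights, 4), collapse = ","),
                " kernel weights=",
                paste(signif(res$selection$weights, 4), collapse = ","))
      finish_fit(cfg, cube, res$fit, res$selection)
    },
    elbow = {
      cube <- read_cube(cfg$input)
      curve <- elbow(cube, k_range = 2:cfg$k, seed = cfg$seed)
      log_stage(cfg, "suggested k = ", attr(curve, "suggested_k"))
      if (!is.null(cfg$report)) {
        jsonlite::write_json(
          list(curve = as.data.frame(curve),
               suggested_k = attr(curve, "suggested_k")),
          cfg$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      invisible(curve)
    },
    triplets = {
      triplets <- read_triplets(cfg$input)
      lib_matrix <- do.call(rbind, triplets$reflectance)
      sel <- run_selection(lib_matrix)
      res <- run_triplets(triplets, as_kernel_spec(sel),
                          max_iter = max(cfg$max_iter, 2L),
                          change_threshold = cfg$change_threshold,
                          seed = cfg$seed)
      acc <- mean(res$success)
      log_stage(cfg, "triplet accuracy ", signif(acc, 4), " over ",
                nrow(res), " groups")
      if (!is.null(cfg$report)) {
        jsonlite::write_json(
          list(accuracy = acc, pair = sel$pair,
               weights = as.list(sel$weights), groups = res),
          cfg$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      invisible(list(selection = sel, results = res, accuracy = acc))
    },
    evaluate = {
      pred <- read_class_raster(cfg$input)
      truth <- read_class_raster(cfg$truth)
      report <- evaluate_classification(pred, truth)
      log_stage(cfg, "OA ", signif(report$overall_accuracy, 4), " kappa ",
                signif(report$kappa, 4))
      if (!is.null(cfg$report)) write_eval_report(report, cfg$report)
      invisible(report)
    }
  )
}

finish_fit <- function(cfg, cube, fit, selection) {
  out <- list(fit = fit, selection = selection)
  labels <- matrix(paste0("cluster", fit$labels),
                   nrow(fit$labels), ncol(fit$labels))
  labels[is.na(fit$labels)] <- NA_character_
  if (!is.null(cfg$out)) {
    write_class_raster(labels, cfg$out, geo = cube$geo)
    log_stage(cfg, "classification raster written: ", cfg$out)
  }
  if (!is.null(cfg$truth)) {
    truth <- read_class_raster(cfg$truth)
    out$evaluation <- evaluate_classification(fit$labels, truth)
    log_stage(cfg, "OA ", signif(out$evaluation$overall_accuracy, 4),
              " kappa ", signif(out$evaluation$kappa, 4))
  }
  if (!is.null(cfg$report)) {
    rep <- list()
    if (!is.null(selection)) {
      rep$selection <- list(pair = selection$pair,
                            rho = as.data.frame(selection$rho),
                            cv = as.list(selection$cv),
                            norm_weights = as.list(selection$norm_weights),
                            weights = as.list(selection$weights))
    }
    rep$fit <- list(k = fit$k, iterations = fit$iterations,
                    converged = fit$converged, inertia = fit$inertia,
                    distortion = fit$distortion, seed = fit$seed,
                    changed_fraction = fit$changed_fraction,
                    centroids = as.data.frame(fit$centroids))
    if (!is.null(out$evaluation)) {
      ev <- out$evaluation
      rep$evaluation <- list(overall_accuracy = ev$overall_accuracy,
                             kappa = ev$kappa, macro_f1 = ev$macro_f1,
                             per_class = ev$per_class)
    }
    jsonlite::write_json(rep, cfg$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    log_stage(cfg, "report written: ", cfg$report)
  }
  invisible(out)
}

#' Runtime scaling benchmark
#'
#' Times the end-to-end pipeline (feature extraction, selection and the
#' weighted hybrid fit) on synthetic scenes of increasing size and fits a
#' log-log regression of elapsed seconds on pixel count. Both the feature
#' selection (one visit per pixel and measure) and K-means (pixels x
#' centroids per sweep) are linear in pixel count, so the slope should sit
#' near 1.
#'
#' @param sides Vector of square scene side lengths in pixels.
#' @param n_bands,n_classes Scene parameters.
#' @param k Clusters fitted.
#' @param reps Repetitions per size; the minimum elapsed time is kept to
#'   damp timer noise on small scenes.
#' @param seed RNG seed.
#' @return Tibble with `side`, `pixels`, `seconds`; attribute
#'   `loglog_slope`.
#' @export
runtime_scaling <- function(sides = c(32, 48, 64, 96, 128, 181, 256),
                            n_bands = 30, n_classes = 5, k = 5, reps = 3,
                            seed = 1L) {
  em <- make_endmembers(n_classes, n_bands, seed = seed)
  res <- purrr::map_dfr(sides, function(s) {
    scene <- make_scene(rows = s, cols = s, n_bands = n_bands,
                        n_classes = n_classes, seed = seed,
                        endmembers = em)
    secs <- min(vapply(seq_len(reps), function(r) {
      system.time(
        hcw_ssc(scene$cube, k = k, max_iter = 10, seed = seed + r)
      )[["elapsed"]]
    }, numeric(1)))
    tibble(side = s, pixels = s^2, seconds = secs)
  })
  slope <- unname(stats::coef(
    stats::lm(log(seconds) ~ log(pixels), data = res))[2])
  attr(res, "loglog_slope") <- slope
  res
}
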