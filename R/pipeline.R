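# accept file paths, raster arrays, or synthetic panicles interchangeably
.load_image <- function(x) {
  if (is.character(x)) return(read_panicle_image(x))
  if (inherits(x, "synthetic_panicle")) return(x$image)
  as_raster(x)
}

#' Extract counting features from one image
#'
#' Convenience wrapper: preprocess, then compute the pixel-fraction
#' features of the stem-free mask against the original image area.
#'
#' @param img image path, `H x W x 3` array, or `synthetic_panicle`.
#' @param cfg a [preprocess_config()]; by default scaled to the image size
#'   via [scaled_preprocess_config()].
#' @return a `panicle_features` object.
#' @export
image_features <- function(img, cfg = NULL) {
  img <- .load_image(img)
  if (is.null(cfg)) cfg <- scaled_preprocess_config(dim(img)[1:2])
  res <- preprocess_image(img, cfg)
  compute_features(res$stemless_mask, prod(dim(img)[1:2]),
                   connectivity = cfg$connectivity)
}

#' Fit and validate a counting model from images
#'
#' End-to-end workflow: preprocess every image, extract features, fit the
#' min-max normalizer and the linear counting model on the training split,
#' and evaluate rounded predictions on the held-out split. The split is
#' deterministic given `seed`.
#'
#' @param images list/vector of image paths, arrays or `synthetic_panicle`s.
#' @param counts true grain counts, one per image.
#' @param cfg a [preprocess_config()] (default: scaled to the first image).
#' @param terms model terms, ordered subset of `c("cd", "sk", "co")`.
#' @param group optional group key (subspecies, device, shape) stored with
#'   the model.
#' @param val_fraction held-out fraction (default 0.25).
#' @param seed integer seed for the split.
#' @param out_dir optional directory; writes `model.json`, `features.csv`
#'   and `report.json` when given.
#' @return list with `model` (`count_model` incl. norm stats), `report`
#'   (validation `eval_report`), `features` (feature table with
#'   normalized columns, counts and split), and `predictions`.
#' @export
run_pipeline <- function(images, counts, cfg = NULL, terms = "cd",
                         group = NULL, val_fraction = 0.25, seed = 1L,
                         out_dir = NULL) {
  n <- length(images)
  if (n < 4) stop("need at least 4 training images with counts")
  if (length(counts) != n) stop("counts must match images")
  fvs <- vector("list", n)
  for (i in seq_len(n)) {
    fvs[[i]] <- tryCatch(image_features(images[[i]], cfg), error = function(e)
      stop("feature extraction failed for image ", i, ": ", conditionMessage(e)))
  }
  ft <- feature_table(fvs)
  ft$true_count <- counts
  set.seed(seed)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  ft$split <- ifelse(seq_len(n) %in% val_idx, "validation", "train")
  train <- ft[ft$split == "train", ]
  stats <- fit_normalizer(train, group = group)
  ftn <- normalize_features(ft, stats)
  model <- fit_count_model(ftn[ftn$split == "train", ],
                           train$true_count, terms = terms,
                           group = group, norm_stats = stats)
  val <- ftn[ftn$split == "validation", ]
  pred <- predict_count(model, val)
  pred <- cbind(image_id = val$image_id, pred, true_count = val$true_count)
  report <- evaluate_model(pred$gn_count, pred$true_count)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_model(model, file.path(out_dir, "model.json"))
    write.csv(ftn, file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, report = report, features = ftn, predictions = pred)
}

#' Count grains on new images with a fitted model
#'
#' @param images list/vector of image paths, arrays or `synthetic_panicle`s
#'   (may be empty).
#' @param model a `count_model` carrying `norm_stats`.
#' @param cfg optional [preprocess_config()].
#' @param image_id optional identifiers.
#' @return data frame with one row per image: `image_id`, `cd`, `sk`, `co`,
#'   `gn_raw`, `gn_count`.
#' @export
count_images <- function(images, model, cfg = NULL, image_id = NULL) {
  stopifnot(inherits(model, "count_model"))
  if (is.null(model$norm_stats))
    stop("model carries no normalization statistics")
  if (length(images) == 0)
    return(data.frame(image_id = character(0), cd = numeric(0),
                      sk = numeric(0), co = numeric(0),
                      gn_raw = numeric(0), gn_count = numeric(0)))
  fvs <- lapply(images, image_features, cfg = cfg)
  ft <- feature_table(fvs, image_id = image_id)
  ftn <- normalize_features(ft, model$norm_stats)
  pred <- predict_count(model, ftn)
  cbind(ft[, c("image_id", "cd", "sk", "co")], pred)
}

#' Synthetic train/validation counting experiment
#'
#' The package's reference experiment: generate a synthetic dataset,
#' run the full pipeline (preprocess, features, normalization, linear
#' model) on a train split, and score rounded predictions on a validation
#' split. Images are rendered, processed and discarded one at a time, so
#' memory stays flat. Deterministic given `seed`.
#'
#' @param n_train,n_val split sizes.
#' @param image_size `c(H, W)` of the rendered frames.
#' @param terms model terms (default the univariate coverage-degree model).
#' @param seed dataset seed.
#' @param remove_stem logical, passed to the preprocess configuration.
#' @param cfg optional [preprocess_config()] override.
#' @param ... forwarded to [dataset_specs()] (shape, subspecies,
#'   count_range, overlap_prob, ...).
#' @return list with `model`, `report` (validation `eval_report`),
#'   `train_report`, `features` and `predictions`.
#' @export
run_count_experiment <- function(n_train = 160, n_val = 100,
                                 image_size = c(620, 877), terms = "cd",
                                 seed = 42L, remove_stem = TRUE, cfg = NULL,
                                 ...) {
  specs <- dataset_specs(n_train + n_val, seed = seed,
                         image_size = image_size, ...)
  if (is.null(cfg))
    cfg <- scaled_preprocess_config(image_size, remove_stem = remove_stem)
  s_im <- prod(image_size)
  n <- length(specs)
  fvs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- render_panicle(specs[[i]])
    res <- preprocess_image(p$image, cfg)
    fvs[[i]] <- compute_features(res$stemless_mask, s_im,
                                 connectivity = cfg$connectivity)
  }
  ft <- feature_table(fvs)
  ft$true_count <- vapply(specs, `[[`, 0L, "n_grains")
  ft$split <- rep(c("train", "validation"), c(n_train, n_val))
  train <- ft[ft$split == "train", ]
  stats <- fit_normalizer(train)
  ftn <- normalize_features(ft, stats)
  model <- fit_count_model(ftn[ftn$split == "train", ], train$true_count,
                           terms = terms, norm_stats = stats)
  val <- ftn[ftn$split == "validation", ]
  pred <- predict_count(model, val)
  pred <- cbind(image_id = val$image_id, pred, true_count = val$true_count)
  report <- evaluate_model(pred$gn_count, pred$true_count)
  train_pred <- predict_count(model, ftn[ftn$split == "train", ])
  train_report <- evaluate_model(train_pred$gn_count, train$true_count)
  list(model = model, report = report, train_report = train_report,
       features = ftn, predictions = pred)
}
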