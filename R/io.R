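read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    x <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path)
  } else if (ext %in% c("nii", "gz")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI input requires the RNifti package")
    }
    x <- as.array(RNifti::readNifti(path))
    if (length(dim(x)) == 3 && dim(x)[3] == 1) x <- x[, , 1]
    mx <- max(abs(x))
    if (mx > 0) x <- x / mx
  } else {
    stop(sprintf("unsupported image format: %s", path))
  }
  if (length(dim(x)) == 3) x <- x[, , 1]  # first channel of multi-channel input
  as.matrix(x)
}

#' Read an image/mask pair
#'
#' Reads a grayscale image (PNG/TIFF, optionally single-slice NIfTI) scaled
#' to \[0,1\] and its mask binarized at > 0. PNG/TIFF values are already
#' dtype-scaled to \[0,1\] by the readers (a {0,255} 8-bit mask maps to
#' {0,1}).
#'
#' @param image_path,mask_path file paths.
#' @return list with `image` (numeric matrix in \[0,1\]) and `mask` (binary
#'   matrix).
#' @export
read_image_mask_pair <- function(image_path, mask_path) {
  image <- read_gray(image_path)
  mask <- 1 * (read_gray(mask_path) > 0)
  if (!all(dim(image) == dim(mask))) {
    stop(sprintf("shape mismatch: image %s is %s but mask %s is %s",
                 image_path, paste(dim(image), collapse = "x"),
                 mask_path, paste(dim(mask), collapse = "x")))
  }
  list(image = image, mask = mask)
}

#' Write a mask or image as PNG
#'
#' Masks (all values 0/1) round-trip bit-exactly through 8-bit PNG.
#'
#' @param x numeric matrix in \[0,1\].
#' @param path output path.
#' @export
write_png <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Write a per-case metrics report
#'
#' CSV with one row per case plus a final `Mean` row (column means over
#' defined cases, 4 decimal places; missing Hausdorff values serialize as
#' empty cells), and a JSON aggregate of the means next to it.
#'
#' @param reports data.frame as produced by [evaluate_case()] rows (or the
#'   `cases` element of [evaluate_batch()]).
#' @param path CSV output path; the JSON aggregate replaces the extension.
#' @param miou optional aggregate mIoU to include in the JSON.
#' @return invisibly, a list with the csv and json paths.
#' @export
write_report <- function(reports, path, miou = NULL) {
  cols <- c("case", "dice", "precision", "specificity", "iou", "pa", "hausdorff")
  if (nrow(reports) > 0) {
    reports <- reports[, cols]
    means <- colMeans(reports[, -1, drop = FALSE], na.rm = TRUE)
    num <- cbind(reports[, -1, drop = FALSE])
    out <- data.frame(case = c(as.character(reports$case), "Mean"),
                      rbind(round(num, 4), round(t(means), 4)))
  } else {
    out <- data.frame(case = character(), dice = numeric(),
                      precision = numeric(), specificity = numeric(),
                      iou = numeric(), pa = numeric(), hausdorff = numeric())
    means <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  json_path <- sub("\\.[^.]*$", ".json", path)
  agg <- as.list(means)
  if (!is.null(miou)) agg$miou <- miou
  jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = path, json = json_path))
}

#' Read a run configuration from YAML
#'
#' Recognized blocks: `loss` (name plus [loss_config()] fields, `lambda_*`,
#' `gamma`, `alpha`, `epsilon` for the compound spec; `o`, `margin`,
#' `embed_dim` for the shape spec), `augmentation` ([augmentation_spec()]
#' fields), `model` ([model_config()] fields), and scalars `threshold` and
#' `seed`.
#'
#' @param path YAML file path.
#' @return list with `loss`, `augmentation`, `model`, `threshold`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(block, fn) {
    if (is.null(block)) return(fn())
    do.call(fn, block[intersect(names(block), names(formals(fn)))])
  }
  lc <- loss_config()
  if (!is.null(y$loss)) {
    lb <- y$loss
    comp <- pick(lb, compound_spec)
    shp <- pick(lb, shape_spec)
    args <- lb[intersect(names(lb), names(formals(loss_config)))]
    args$compound <- comp; args$shape <- shp
    lc <- do.call(loss_config, args)
  }
  list(loss = lc,
       augmentation = pick(y$augmentation, augmentation_spec),
       model = pick(y$model, model_config),
       threshold = if (is.null(y$threshold)) 0.5 else y$threshold,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

#' Write a provenance block alongside run outputs
#'
#' Records the package version, seed, timestamp and a hash of the
#' configuration so every CLI run is traceable.
#'
#' @param dir output directory.
#' @param seed seed used by the run.
#' @param config any serializable configuration object.
#' @return invisibly, the provenance file path.
#' @export
write_provenance <- function(dir, seed, config = NULL) {
  prov <- list(
    package = "boundseg",
    version = as.character(utils::packageVersion("boundseg")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = if (is.null(config)) NA else
      sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE)
  invisible(path)
}
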