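#' Save / load trained models
#'
#' Checkpoints are a documented container (format tag, model class,
#' package version, the topology and parameter tensors) serialized with
#' `saveRDS`.
#'
#' @param model a `patch_classifier` or `baa_classifier`.
#' @param path checkpoint path.
#' @return `path` invisibly for the writer; the model for the loader.
#' @export
save_baa_model <- function(model, path) {
  if (!inherits(model, c("patch_classifier", "baa_classifier")))
    baa_stop("baa_config_error", "not a saveable model")
  saveRDS(list(format = "autobaa-checkpoint-1",
               model_class = class(model)[1],
               package_version = as.character(utils::packageVersion("autobaa")),
               model = model), path)
  invisible(path)
}

#' @rdname save_baa_model
#' @export
load_baa_model <- function(path) {
  if (!file.exists(path))
    baa_stop("baa_config_error", sprintf("model file not found: %s", path))
  x <- readRDS(path)
  if (!identical(x$format, "autobaa-checkpoint-1"))
    baa_stop("baa_format_error", "not an autobaa checkpoint")
  x$model
}

#' Run the full assessment pipeline on one radiograph
#'
#' Normalization (grayscale base, size), sliding-window label map, hand
#' mask, vision pipeline, bone-age prediction, structured report. Fully
#' deterministic: repeated runs on the same input and models give the
#' same assessment.
#'
#' @param input radiograph path (PNG/DICOM) or a [radiograph()].
#' @param detector path to a saved patch detector or a `patch_classifier`.
#' @param classifier path to a saved classifier or a `baa_classifier`.
#' @param stride sliding-window stride for the label map.
#' @param topk number of reference suggestions (clamped to 3..5).
#' @param keep_intermediates attach normalized image, label map, mask and
#'   preprocessed image to the report (attribute `"intermediates"`).
#' @return an object of class `baa_report`.
#' @export
run_pipeline <- function(input, detector, classifier, stride = 4L,
                         topk = 5L, keep_intermediates = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, baa_error = function(e) {
      baa_stop(class(e)[1],
               sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  rg <- stage("input", {
    if (inherits(input, "radiograph")) input else read_radiograph(input)
  })
  det <- stage("detector", {
    if (inherits(detector, "patch_classifier")) detector
    else load_baa_model(detector)
  })
  if (!inherits(det, "patch_classifier"))
    baa_stop("baa_config_error", "[detector] checkpoint is not a patch classifier")
  clf <- stage("classifier", {
    if (inherits(classifier, "baa_classifier")) classifier
    else load_baa_model(classifier)
  })
  if (!inherits(clf, "baa_classifier"))
    baa_stop("baa_config_error", "[classifier] checkpoint is not a bone-age classifier")

  norm <- stage("normalize", normalize_size(normalize_grayscale_base(rg)))
  lm <- stage("label-map",
              build_label_map(norm, det, patch_size = det$patch_size,
                              stride = stride))
  mask <- stage("mask", generate_mask(labelmap_to_hand(lm)))
  pre <- stage("vision-pipeline", vision_pipeline(norm, mask))
  pred <- stage("predict", predict(clf, pre, topk = 5L))

  sex <- if (!is.na(rg$sex)) rg$sex else clf$sex
  report <- structured_report(
    source_id = rg$source_id, sex = sex, prediction = pred, topk = topk,
    pipeline_versions = c(
      autobaa = as.character(utils::packageVersion("autobaa")),
      detector = model_fingerprint(detector),
      classifier = model_fingerprint(classifier)))
  if (keep_intermediates)
    attr(report, "intermediates") <- list(normalized = norm, label_map = lm,
                                          mask = mask, preprocessed = pre)
  report
}

model_fingerprint <- function(m) {
  if (is.character(m) && file.exists(m)) unname(tools::md5sum(m))
  else sprintf("in-memory-%s", class(m)[1])
}

#' Assemble a structured bone-age report
#'
#' @param source_id study identifier.
#' @param sex cohort.
#' @param prediction a [predict.baa_classifier()] result.
#' @param topk requested number of reference suggestions; values outside
#'   3..5 are clamped with a warning (the report offers three to five
#'   atlas reference ages).
#' @param pipeline_versions named character vector of component versions.
#' @return an object of class `baa_report`.
#' @export
structured_report <- function(source_id, sex, prediction, topk = 5L,
                              pipeline_versions = character(0)) {
  stopifnot(inherits(prediction, "bone_age_prediction"))
  if (topk < 3L || topk > 5L) {
    baa_warn("baa_topk_clamped",
             sprintf("topk %d outside 3..5; clamped", topk))
    topk <- clip(topk, 3L, 5L)
  }
  structure(list(
    source_id = source_id, sex = sex,
    predicted_bone_age = prediction$top1,
    topk_suggestions = head(prediction$topk, topk),
    maturity_stage = as.character(maturity_stage(sex, prediction$top1)),
    probabilities = prediction$probabilities,
    pipeline_versions = as.list(pipeline_versions),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "baa_report")
}

#' Serialize a structured report
#'
#' @param r a `baa_report`.
#' @param format `"json"` (schema-stable, round-trips through
#'   [parse_report()]) or `"text"` (human-readable, with the top-k table).
#' @return character scalar.
#' @export
render_report <- function(r, format = c("json", "text")) {
  stopifnot(inherits(r, "baa_report"))
  if (!format[1] %in% c("json", "text"))
    baa_stop("baa_config_error", sprintf("unknown format '%s'", format[1]))
  format <- match.arg(format)
  if (format == "json") {
    body <- unclass(r)
    body$topk_suggestions <- as.data.frame(r$topk_suggestions)
    body$probabilities <- as.list(r$probabilities)
    return(as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA)))
  }
  k <- nrow(r$topk_suggestions)
  paste0(
    sprintf("Automated bone age assessment\n  study: %s\n  sex: %s\n",
            r$source_id, r$sex),
    sprintf("  predicted bone age: %d years\n  maturity stage: %s\n",
            r$predicted_bone_age, gsub("_", "-", r$maturity_stage)),
    sprintf("  reference suggestions (top %d):\n", k),
    paste(sprintf("    %2d years  p=%.4f", r$topk_suggestions$bone_age,
                  r$topk_suggestions$probability), collapse = "\n"),
    "\n")
}

#' @rdname render_report
#' @param json a JSON string produced by `render_report(format = "json")`.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(
    source_id = x$source_id, sex = x$sex,
    predicted_bone_age = as.integer(x$predicted_bone_age),
    topk_suggestions = data.frame(bone_age = as.integer(x$topk_suggestions$bone_age),
                                  probability = x$topk_suggestions$probability),
    maturity_stage = x$maturity_stage,
    probabilities = {
      p <- unlist(x$probabilities)
      names(p) <- names(x$probabilities)
      p
    },
    pipeline_versions = x$pipeline_versions,
    timestamp = x$timestamp), class = "baa_report")
}

#' @export
print.baa_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}
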