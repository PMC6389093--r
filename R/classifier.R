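# Pluggable logistic classifier for the probability that a referral is a
# true TIA/minor stroke rather than a mimic. The model is fully
# configuration-driven: intercept, main-effect coefficients, interaction
# coefficients, and a codebook mapping feature names onto referral fields.

#' Construct a clinical classifier model
#'
#' A logistic model `logit(p) = intercept + sum(b_j x_j) + sum(g_k x_a x_b)`.
#' Feature encoding is governed by the codebook: a feature is either a form
#' checkbox (`symptom`, encoded 0/1 with absent = 0) or a continuous referral
#' field (`field`, e.g. age). Features without a codebook entry default to
#' symptom checkboxes of the same name.
#'
#' @param intercept numeric intercept.
#' @param main_effects named numeric vector of main-effect coefficients.
#' @param interactions list of `list(features = c(a, b), coef = g)` entries;
#'   interaction features must be declared as main effects or in the codebook.
#' @param codebook named list; each entry is `list(type = "symptom")` or
#'   `list(type = "field", field = "<referral column>")`.
#' @param expected_mains,expected_interactions declared term counts; a
#'   mismatch between declared and actual counts raises a structure warning,
#'   not an error, so truncated configs are caught early.
#' @return an object of class `classifier_model`.
#' @export
classifier_model <- function(intercept, main_effects, interactions = list(),
                             codebook = list(), expected_mains = NULL,
                             expected_interactions = NULL) {
  if (!is.numeric(intercept) || length(intercept) != 1L || is.na(intercept)) {
    stop("intercept must be a single numeric value", call. = FALSE)
  }
  main_effects <- unlist(main_effects)
  if (is.null(names(main_effects)) || any(names(main_effects) == "")) {
    stop("every main effect must be named", call. = FALSE)
  }
  if (any(is.na(suppressWarnings(as.numeric(main_effects))))) {
    bad <- names(main_effects)[is.na(suppressWarnings(as.numeric(main_effects)))]
    stop(sprintf("non-numeric coefficient for main effect(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  main_effects <- stats::setNames(as.numeric(main_effects), names(main_effects))
  known <- union(names(main_effects), names(codebook))
  interactions <- lapply(interactions, function(it) {
    if (length(it$features) != 2L) {
      stop("each interaction must name exactly two features", call. = FALSE)
    }
    unknown <- setdiff(it$features, known)
    if (length(unknown)) {
      stop(sprintf("interaction references undeclared feature(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (is.null(it$coef) || is.na(suppressWarnings(as.numeric(it$coef)))) {
      stop(sprintf("non-numeric coefficient for interaction %s:%s",
                   it$features[1], it$features[2]), call. = FALSE)
    }
    list(features = as.character(it$features), coef = as.numeric(it$coef))
  })
  if (!is.null(expected_mains) && length(main_effects) != expected_mains) {
    warning(sprintf("model structure: %d main effects found, %d declared",
                    length(main_effects), expected_mains), call. = FALSE)
  }
  if (!is.null(expected_interactions) &&
      length(interactions) != expected_interactions) {
    warning(sprintf("model structure: %d interactions found, %d declared",
                    length(interactions), expected_interactions),
            call. = FALSE)
  }
  structure(list(intercept = intercept, main_effects = main_effects,
                 interactions = interactions, codebook = codebook),
            class = "classifier_model")
}

#' Load a classifier model from a YAML config file
#'
#' The file declares `intercept`, a `main_effects` name-to-coefficient map,
#' an `interactions` list (`features` pair plus `coef`), an optional
#' `codebook`, and optional `expected_mains` / `expected_interactions`
#' counts for the structure audit.
#'
#' @param path YAML file path.
#' @return a [classifier_model()].
#' @export
#' @examples
#' m <- read_classifier_model(tiaqueue_example("example_classifier.yaml"))
#' model_audit(m)
read_classifier_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$intercept) || is.null(cfg$main_effects)) {
    stop(sprintf("%s: classifier config must declare intercept and main_effects",
                 path), call. = FALSE)
  }
  classifier_model(
    intercept = cfg$intercept,
    main_effects = cfg$main_effects,
    interactions = cfg$interactions %||% list(),
    codebook = cfg$codebook %||% list(),
    expected_mains = cfg$expected_mains,
    expected_interactions = cfg$expected_interactions
  )
}

#' Audit a classifier model's structure
#'
#' Reports term counts and how many coefficients are positive (i.e.
#' predictive of TIA/minor stroke), for comparison against a model's
#' published structure.
#'
#' @param model a [classifier_model()].
#' @return list with `n_mains`, `n_interactions`, `n_positive_mains`,
#'   `n_positive_interactions`.
#' @export
model_audit <- function(model) {
  stopifnot(inherits(model, "classifier_model"))
  icoefs <- vapply(model$interactions, function(it) it$coef, numeric(1))
  list(
    n_mains = length(model$main_effects),
    n_interactions = length(model$interactions),
    n_positive_mains = sum(model$main_effects > 0),
    n_positive_interactions = sum(icoefs > 0)
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  a <- model_audit(x)
  cat(sprintf(paste0("<classifier_model> %d main effects (%d positive), ",
                     "%d interactions (%d positive)\n"),
              a$n_mains, a$n_positive_mains, a$n_interactions,
              a$n_positive_interactions))
  invisible(x)
}

# Encode one feature for all rows of a referral table.
encode_feature <- function(df, feature, codebook) {
  entry <- codebook[[feature]] %||% list(type = "symptom")
  if (identical(entry$type, "field")) {
    col <- entry$field %||% feature
    if (!col %in% names(df)) {
      stop(sprintf("feature '%s': referral field '%s' not present",
                   feature, col), call. = FALSE)
    }
    v <- df[[col]]
    if (anyNA(v)) {
      stop(sprintf("feature '%s': missing value in field '%s' (value NA)",
                   feature, col), call. = FALSE)
    }
    as.numeric(v)
  } else {
    as.numeric(symptom_indicator(df, feature))
  }
}

#' Predict the probability of TIA/minor stroke
#'
#' Evaluates the linear predictor term by term and maps it through the
#' logistic link (computed in a numerically stable form, so extreme
#' predictors saturate rather than overflow).
#'
#' @param model a [classifier_model()].
#' @param x a [referral_cohort()] or referral data frame; absent symptom
#'   checkboxes encode as 0.
#' @return data frame with `id`, `linear_predictor`, `p_tia`.
#' @export
predict_tia_probability <- function(model, x) {
  stopifnot(inherits(model, "classifier_model"))
  df <- if (inherits(x, "referral_cohort")) x$referrals else x
  lp <- rep(model$intercept, nrow(df))
  enc <- new.env(parent = emptyenv())
  get_enc <- function(f) {
    if (!exists(f, envir = enc, inherits = FALSE)) {
      assign(f, encode_feature(df, f, model$codebook), envir = enc)
    }
    get(f, envir = enc, inherits = FALSE)
  }
  for (f in names(model$main_effects)) {
    lp <- lp + model$main_effects[[f]] * get_enc(f)
  }
  for (it in model$interactions) {
    lp <- lp + it$coef * get_enc(it$features[1]) * get_enc(it$features[2])
  }
  data.frame(id = df$id, linear_predictor = lp,
             p_tia = stats::plogis(lp), stringsAsFactors = FALSE)
}

#' Path to a bundled example/config file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
tiaqueue_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tiaqueue")))
  }
  path <- system.file("extdata", file, package = "tiaqueue")
  if (path == "") stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  path
}
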