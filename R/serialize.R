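#' Write a flux dataset as CSV
#'
#' Label columns (`carbon`, `nitrogen`, `replicate`, `biomass`) followed by
#' one column per internal reaction.
#'
#' @param dataset a `flux_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_dataset <- function(dataset, path) {
  df <- data.frame(carbon = dataset$carbon, nitrogen = dataset$nitrogen,
                   replicate = dataset$replicate, biomass = dataset$biomass,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(dataset$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flux dataset written by [write_flux_dataset()]
#'
#' @param path CSV path.
#' @return A `flux_dataset`.
#' @export
read_flux_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  label_cols <- c("carbon", "nitrogen", "replicate", "biomass")
  if (!all(label_cols %in% names(df)))
    stop("flux dataset CSV lacks label columns: ",
         paste(setdiff(label_cols, names(df)), collapse = ", "))
  internal <- setdiff(names(df), label_cols)
  X <- as.matrix(df[internal])
  rownames(X) <- NULL
  structure(list(X = X,
                 carbon = df$carbon, nitrogen = df$nitrogen,
                 biomass = df$biomass, replicate = df$replicate,
                 impurities = vector("list", nrow(df)),
                 internal_ids = internal),
            class = "flux_dataset")
}

#' Serialize a trained classifier to JSON
#'
#' Stores classes, intercepts, the nonzero coefficients at the selected
#' penalty as (class, reaction, value) triplets, the penalty, and the
#' feature ids — everything [predict.flux_classifier()] needs. The full
#' glmnet path is not kept.
#'
#' @param classifier a `flux_classifier`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(classifier, path) {
  cf <- classifier_coefficients(classifier)
  nz <- do.call(rbind, lapply(names(cf), function(cl) {
    b <- cf[[cl]]
    keep <- b != 0
    if (!any(keep)) return(NULL)
    data.frame(class = cl, reaction = names(b)[keep], value = unname(b[keep]))
  }))
  doc <- list(classes = classifier$classes,
              feature_ids = classifier$feature_ids,
              lambda_selected = classifier$lambda_selected,
              intercepts = as.list(attr(cf, "intercepts")),
              coefficients = if (is.null(nz)) list() else nz,
              n_folds = classifier$n_folds, seed = classifier$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a classifier serialized by [write_classifier_json()]
#'
#' @param path JSON path.
#' @return A `flux_classifier` backed by stored coefficients (no glmnet
#'   path object); [predict.flux_classifier()] and [predictive_reactions()]
#'   work on it unchanged.
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  feats <- doc$feature_ids
  coefs <- lapply(doc$classes, function(cl) {
    b <- stats::setNames(rep(0, length(feats)), feats)
    tr <- doc$coefficients
    if (length(tr) && nrow(tr)) {
      sel <- tr$class == cl
      b[tr$reaction[sel]] <- tr$value[sel]
    }
    b
  })
  names(coefs) <- doc$classes
  attr(coefs, "intercepts") <- stats::setNames(unlist(doc$intercepts),
                                               doc$classes)
  structure(list(classes = doc$classes, fit = NULL,
                 lambda = doc$lambda_selected,
                 lambda_selected = doc$lambda_selected,
                 cv_misclassification = NULL,
                 feature_ids = feats, n_folds = doc$n_folds, seed = doc$seed,
                 stored_coefficients = coefs),
            class = "flux_classifier")
}

#' Serialize a growth environment to JSON (provenance record)
#'
#' @param env a [growth_environment()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_environment_json <- function(env, path) {
  jsonlite::write_json(unclass(env), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
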