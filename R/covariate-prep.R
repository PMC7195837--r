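#' Covariate specification
#'
#' Metadata for one covariate of a gradient survey: its name, original units,
#' the divisor used to rescale it to an ecologically interpretable unit (e.g.
#' altitude in metres divided by 100 so a coefficient reads "per 100 m"), and
#' its role in the analysis.
#'
#' @param name covariate name
#' @param divisor positive rescaling divisor; the prepared value is
#'   `value / divisor`
#' @param role one of `"pollutant"`, `"climate"`, `"terrain"`, `"soil"`,
#'   `"management"`
#' @param original_units free-text units of the raw values
#' @return an object of class `covariate_spec`
#' @examples
#' covariate_spec("altitude", divisor = 100, role = "terrain",
#'                original_units = "m")
#' @export
covariate_spec <- function(name, divisor = 1, role = "climate",
                           original_units = "") {
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop_("divisor for '%s' must be a single positive number", name)
  }
  role <- match.arg(role,
                    c("pollutant", "climate", "terrain", "soil", "management"))
  structure(list(name = name, divisor = divisor, role = role,
                 original_units = original_units),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat(sprintf("covariate '%s' [%s]: / %g (%s)\n",
              x$name, x$role, x$divisor, x$original_units))
  invisible(x)
}

#' Rescale a covariate by its divisor
#'
#' Divides raw covariate values by the spec's divisor and rounds to a given
#' number of decimals for reporting. Rescaling is linear up to the final
#' rounding, so range endpoints of the input map to the rescaled range
#' endpoints (e.g. altitude 0-975 m with divisor 100 becomes 0.00-9.75).
#'
#' @param values numeric vector of raw covariate values
#' @param spec a [covariate_spec()]
#' @param decimals decimals kept in the output; use `Inf` to keep full
#'   precision (internal computations always should)
#' @return rescaled numeric vector
#' @examples
#' sp <- covariate_spec("altitude", divisor = 100, role = "terrain")
#' rescale_covariate(c(0, 975), sp)       # 0.00 9.75
#' @export
rescale_covariate <- function(values, spec, decimals = 2) {
  assert_num(values, "values")
  bad <- which(!is.finite(values) & !is.na(values))
  if (length(bad)) {
    stop_("non-finite covariate value for '%s' at row(s) %s",
          spec$name, paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- values / spec$divisor
  if (is.finite(decimals)) out <- round(out, decimals)
  out
}

#' Screen a design matrix for collinear pairs
#'
#' Reports all pairs of columns whose absolute Pearson correlation exceeds a
#' threshold, sorted by decreasing |r|. Nothing is dropped: strongly collinear
#' pollutant pairs (total N and total S deposition) are deliberately retained
#' in the models because of their intrinsic interest, and collinearity
#' inflates variance rather than biasing coefficients.
#'
#' @param X numeric matrix or data frame of covariate columns
#' @param threshold report pairs with |r| above this value (in (0,1))
#' @return data frame with columns `var1`, `var2`, `r`; attribute
#'   `"zero_variance"` names any constant columns excluded from screening
#' @export
correlation_screen <- function(X, threshold = 0.7) {
  X <- as.matrix(X)
  if (ncol(X) < 2L || nrow(X) < 3L) {
    stop_("correlation screening needs at least 2 columns and 3 rows")
  }
  if (threshold <= 0 || threshold >= 1) stop_("threshold must be in (0,1)")
  sds <- apply(X, 2, sd)
  zv <- colnames(X)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(colnames(X), zv)
  out <- data.frame(var1 = character(), var2 = character(), r = numeric())
  if (length(keep) >= 2L) {
    R <- cor(X[, keep, drop = FALSE])
    idx <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- data.frame(var1 = keep[idx[, 1]], var2 = keep[idx[, 2]],
                        r = R[idx])
      out <- out[order(-abs(out$r)), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "zero_variance") <- zv
  out
}

#' Mean-impute missing values
#'
#' Replaces missing entries by the mean of the observed entries of the same
#' column (the treatment applied to the plots with unavailable potential
#' evapotranspiration before the climate PCA).
#'
#' @param values numeric vector, possibly with `NA`s
#' @param name column name used in error messages
#' @return vector with `NA`s replaced by the observed mean; attribute
#'   `"n_imputed"` records how many
#' @export
mean_impute <- function(values, name = "value") {
  assert_num(values, "values")
  miss <- is.na(values)
  if (all(miss)) stop_("column '%s' has no observed values to impute from", name)
  values[miss] <- mean(values[!miss])
  attr(values, "n_imputed") <- sum(miss)
  values
}

#' PCA of collinear climate covariates
#'
#' Combines a block of strongly intercorrelated climate variables (mean
#' annual PET, mean daily maximum and minimum temperatures, all pairwise
#' r >= 0.78 in the motivating survey) into two orthogonal scores used in
#' their place. Columns are standardized first (correlation-matrix PCA),
#' since the inputs mix units (mm, degrees C); each component's sign is fixed
#' so its loading on the first input column is non-negative, making scores
#' reproducible across platforms.
#'
#' @param Z numeric matrix/data frame of climate columns (typically 4),
#'   already imputed
#' @return list with `scores` (n x 2 matrix, columns `Climate PC1`,
#'   `Climate PC2`), `loadings`, and `variance_fractions` for all components
#' @export
climate_pca <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 3L) stop_("climate PCA needs at least 3 rows")
  if (anyNA(Z)) stop_("climate PCA input contains missing values; impute first")
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) {
    stop_("constant climate column(s) cannot be standardized: %s",
          paste(colnames(Z)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(Z, center = TRUE, scale. = TRUE)
  flip <- ifelse(pc$rotation[1, ] < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  out_scores <- scores[, 1:2, drop = FALSE]
  colnames(out_scores) <- c("Climate PC1", "Climate PC2")
  list(scores = out_scores, loadings = rot, variance_fractions = vf)
}

#' Variance inflation factors
#'
#' Classical VIFs from least-squares auxiliary regressions: for each column m,
#' VIF_m = 1 / (1 - R^2_m) with R^2_m from regressing column m on all other
#' columns plus an intercept. When `group` is supplied, the auxiliary
#' regressions additionally condition on the grouping factor (fixed group
#' intercepts), a proxy for the mixed-model VIF computed with a random
#' intercept per 1-km square.
#'
#' @param X numeric matrix/data frame of covariates
#' @param group optional factor of group (square) memberships
#' @return named numeric vector of VIFs (`Inf` for perfectly collinear
#'   columns)
#' @export
vif <- function(X, group = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) stop_("VIF needs more rows than columns")
  if (any(apply(X, 2, sd) == 0)) stop_("VIF undefined for constant columns")
  vapply(seq_len(ncol(X)), function(m) {
    df <- data.frame(.y = X[, m], X[, -m, drop = FALSE], check.names = FALSE)
    if (!is.null(group)) df$.g <- factor(group)
    fit <- lm(.y ~ ., data = df)
    r2 <- 1 - sum(resid(fit)^2) / sum((X[, m] - mean(X[, m]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

#' Expand a low/medium/high factor into treatment-coded indicators
#'
#' Grazing intensity is recorded as an ordered low/medium/high code; it enters
#' the design matrix as two indicator columns with "low" as the reference.
#'
#' @param x character or factor vector with levels low/medium/high
#' @param name stem for the generated column names
#' @return n x 2 numeric matrix with columns `<name>_medium`, `<name>_high`
#' @export
expand_grazing <- function(x, name = "grazing") {
  lev <- c("low", "medium", "high")
  x <- factor(as.character(x), levels = lev)
  if (anyNA(x)) stop_("grazing codes must be one of %s", paste(lev, collapse = "/"))
  out <- cbind(as.numeric(x == "medium"), as.numeric(x == "high"))
  colnames(out) <- paste0(name, c("_medium", "_high"))
  out
}

#' Prepare an analysis-ready design matrix
#'
#' Applies, in order: mean imputation of flagged columns, divisor rescaling
#' per the covariate specs, optional PCA replacement of a climate block, and
#' expansion of a grazing factor. Returns the design matrix together with a
#' provenance log (what was imputed/rescaled/combined, the collinearity
#' screen and VIFs).
#'
#' @param data data frame holding the raw covariate columns
#' @param specs list of [covariate_spec()]s, one per covariate to include
#' @param pca_columns optional character vector naming columns to replace by
#'   their first two principal-component scores
#' @param impute_columns columns to mean-impute before anything else
#' @param grazing_column optional name of a low/medium/high column to expand
#' @param screen_threshold threshold handed to [correlation_screen()]
#' @param group optional square memberships forwarded to [vif()]
#' @return list with `X` (numeric design matrix, no missing values, stable
#'   column order), `log` (provenance), `screen`, `vifs`, `pca` (or NULL)
#' @export
prepare_design <- function(data, specs, pca_columns = NULL,
                           impute_columns = NULL, grazing_column = NULL,
                           screen_threshold = 0.7, group = NULL) {
  logs <- character()
  for (cl in impute_columns) {
    v <- mean_impute(data[[cl]], cl)
    logs <- c(logs, sprintf("imputed %d missing values in '%s'",
                            attr(v, "n_imputed"), cl))
    data[[cl]] <- as.numeric(v)
  }
  cols <- list()
  for (sp in specs) {
    if (is.null(data[[sp$name]])) stop_("column '%s' not found", sp$name)
    if (!is.null(pca_columns) && sp$name %in% pca_columns) next
    v <- rescale_covariate(data[[sp$name]], sp, decimals = Inf)
    if (sp$divisor != 1) {
      logs <- c(logs, sprintf("rescaled '%s' by 1/%g", sp$name, sp$divisor))
    }
    cols[[sp$name]] <- v
  }
  pca <- NULL
  if (!is.null(pca_columns)) {
    pca <- climate_pca(as.matrix(data[pca_columns]))
    cols[["Climate PC1"]] <- pca$scores[, 1]
    cols[["Climate PC2"]] <- pca$scores[, 2]
    logs <- c(logs, sprintf("replaced (%s) by Climate PC1/PC2 (%.1f%% + %.1f%% variance)",
                            paste(pca_columns, collapse = ", "),
                            100 * pca$variance_fractions[1],
                            100 * pca$variance_fractions[2]))
  }
  if (!is.null(grazing_column)) {
    gz <- expand_grazing(data[[grazing_column]], grazing_column)
    cols[[colnames(gz)[1]]] <- gz[, 1]
    cols[[colnames(gz)[2]]] <- gz[, 2]
    logs <- c(logs, sprintf("expanded '%s' to treatment-coded indicators (reference: low)",
                            grazing_column))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) stop_("design matrix still contains missing values")
  screen <- correlation_screen(X, screen_threshold)
  vifs <- vif(X, group = group)
  list(X = X, log = logs, screen = screen, vifs = vifs, pca = pca)
}
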