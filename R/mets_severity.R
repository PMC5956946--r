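#' Fit one-factor CFA loadings for the MetS severity score
#'
#' Fits a single-factor model to the five MetS components (waist,
#' triglycerides, HDL, SBP, fasting glucose) of a reference sample, by
#' maximum-likelihood factor analysis on transformed, standardized
#' components. The loadings are sign-normalized so that a higher score
#' means worse metabolic status (positive loading on glucose, negative on
#' HDL), and a scale/offset pair is stored so the reference sample scores
#' to mean 0, SD 1.
#'
#' Triglycerides are log-transformed before standardization (they are
#' strongly right-skewed); the other components enter untransformed. The
#' transformation tags are recorded in the returned object and honoured by
#' [mets_z()].
#'
#' @param reference a `cohort` object or a participants data frame holding
#'   the five component columns.
#' @param subgroup subgroup label to fit (one of
#'   `r paste(SUBGROUPS, collapse=", ")`), or `"all"` for a pooled fit.
#' @param min_n minimum complete-case subgroup size (default 200).
#' @return an object of class `mets_loadings` with fields `subgroup`,
#'   `transform`, `mean`, `sd`, `loading` (per component), `scale`,
#'   `offset`, and `degenerate` (TRUE when no common factor was found).
#' @export
fit_cfa_loadings <- function(reference, subgroup = "all", min_n = 200) {
  df <- if (inherits(reference, "cohort")) reference$participants else reference
  if (subgroup != "all") df <- df[df$subgroup == subgroup, , drop = FALSE]
  x <- df[, MET_COMPONENTS, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < min_n) {
    stop("reference subgroup has fewer than ", min_n, " complete cases")
  }
  transform <- c(waist = "identity", triglycerides = "log", hdl = "identity",
                 sbp = "identity", glucose = "identity")
  z <- x
  z$triglycerides <- log(z$triglycerides)
  mu <- vapply(z, mean, numeric(1))
  sd_ <- vapply(z, stats::sd, numeric(1))
  if (any(sd_ <= 0)) stop("degenerate (zero-variance) component")
  zs <- scale(as.matrix(z), center = mu, scale = sd_)

  degenerate <- FALSE
  loading <- stats::setNames(rep(0, 5), MET_COMPONENTS)
  fit <- tryCatch(stats::factanal(zs, factors = 1), error = function(e) e)
  if (inherits(fit, "error")) {
    degenerate <- TRUE
  } else {
    loading[] <- as.numeric(fit$loadings[, 1])
    # sign convention: higher score = worse metabolic status
    if (loading["glucose"] < 0) loading <- -loading
    # a common factor must load on several components; a Heywood-type
    # single-variable factor or uniformly tiny loadings mean no factor
    if (sum(abs(loading) >= 0.15) < 2) degenerate <- TRUE
  }

  obj <- structure(list(subgroup = subgroup, transform = transform,
                        mean = mu, sd = sd_, loading = loading,
                        scale = 1, offset = 0, degenerate = degenerate),
                   class = "mets_loadings")
  if (!degenerate) {
    raw <- drop(zs %*% loading)
    obj$offset <- mean(raw)
    obj$scale <- stats::sd(raw)
  }
  obj
}

#' Score participants with a MetS severity scoring equation
#'
#' Applies the linear scoring equation held in a `mets_loadings` object:
#' each component is transformed (identity or log), standardized by the
#' reference constants, weighted by its loading, summed, and rescaled so a
#' reference-sample score has mean 0 and SD 1.
#'
#' @param components a data frame (or cohort) with the five component
#'   columns, or a named numeric vector for a single participant.
#' @param loadings a `mets_loadings` object.
#' @return numeric vector of MetS severity Z-scores (SD units).
#' @export
mets_z <- function(components, loadings) {
  stopifnot(inherits(loadings, "mets_loadings"))
  if (inherits(components, "cohort")) components <- components$participants
  if (is.numeric(components) && !is.null(names(components))) {
    components <- as.data.frame(as.list(components))
  }
  miss <- setdiff(MET_COMPONENTS, names(components))
  if (length(miss)) stop("missing component column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(components[, MET_COMPONENTS, drop = FALSE])
  if (anyNA(x)) stop("missing MetS component value: participants with missing components must be excluded")
  for (k in MET_COMPONENTS) {
    if (loadings$transform[k] == "log") {
      if (any(x[, k] <= 0)) stop("non-positive value for log-transformed component ", k)
      x[, k] <- log(x[, k])
    }
  }
  zs <- sweep(sweep(x, 2, loadings$mean[MET_COMPONENTS]), 2,
              loadings$sd[MET_COMPONENTS], "/")
  raw <- drop(zs %*% loadings$loading[MET_COMPONENTS])
  unname((raw - loadings$offset) / loadings$scale)
}

#' Score a cohort subgroup-by-subgroup
#'
#' Fits (or applies) per-subgroup scoring equations and returns a MetS
#' severity Z for every participant, using each participant's own
#' subgroup's equation.
#'
#' @param cohort a `cohort` object (typically the analytic sample).
#' @param loadings_list optional named list of `mets_loadings` per subgroup;
#'   fitted from `cohort` itself when `NULL`.
#' @return list with `score` (numeric, aligned to participants) and
#'   `loadings` (the per-subgroup equations used).
#' @export
score_mets_cohort <- function(cohort, loadings_list = NULL, min_n = 200) {
  df <- cohort$participants
  if (is.null(loadings_list)) {
    # subgroups too small for a stable factor fit fall back to the pooled
    # equation
    pooled <- NULL
    loadings_list <- lapply(stats::setNames(SUBGROUPS, SUBGROUPS), function(g) {
      n_g <- sum(df$subgroup == g &
                   stats::complete.cases(df[, MET_COMPONENTS, drop = FALSE]))
      if (n_g >= min_n) return(fit_cfa_loadings(cohort, g, min_n = min_n))
      if (is.null(pooled)) pooled <<- fit_cfa_loadings(cohort, "all",
                                                       min_n = min_n)
      message("subgroup ", g, " has ", n_g,
              " complete cases; using the pooled scoring equation")
      pooled
    })
  }
  score <- rep(NA_real_, nrow(df))
  for (g in names(loadings_list)) {
    idx <- which(df$subgroup == g)
    if (length(idx)) score[idx] <- mets_z(df[idx, , drop = FALSE], loadings_list[[g]])
  }
  list(score = score, loadings = loadings_list)
}

#' HOMA-IR insulin resistance index
#'
#' Homeostasis model assessment of insulin resistance:
#' `fasting insulin (mU/L) * fasting glucose (mg/dL) / 405`.
#'
#' @param fasting_insulin insulin in mU/L (>= 0).
#' @param fasting_glucose glucose in mg/dL (> 0).
#' @return numeric HOMA-IR value(s).
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(fasting_insulin < 0, na.rm = TRUE)) stop("insulin must be >= 0")
  if (any(fasting_glucose <= 0, na.rm = TRUE)) stop("glucose must be > 0")
  fasting_insulin * fasting_glucose / 405
}

#' Serialize / deserialize MetS scoring equations as YAML
#'
#' @param loadings a `mets_loadings` object or a named list of them.
#' @param path file path for the YAML.
#' @return `write_mets_loadings()` returns `path` invisibly;
#'   `read_mets_loadings()` the object(s).
#' @export
write_mets_loadings <- function(loadings, path) {
  as_plain <- function(l) list(subgroup = l$subgroup,
                               transform = as.list(l$transform),
                               mean = as.list(l$mean), sd = as.list(l$sd),
                               loading = as.list(l$loading),
                               scale = l$scale, offset = l$offset,
                               degenerate = l$degenerate)
  obj <- if (inherits(loadings, "mets_loadings")) as_plain(loadings) else
    lapply(loadings, as_plain)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_mets_loadings
#' @export
read_mets_loadings <- function(path) {
  raw <- yaml::read_yaml(path)
  from_plain <- function(r) {
    structure(list(subgroup = r$subgroup,
                   transform = unlist(r$transform),
                   mean = unlist(r$mean), sd = unlist(r$sd),
                   loading = unlist(r$loading),
                   scale = r$scale, offset = r$offset,
                   degenerate = isTRUE(r$degenerate)),
              class = "mets_loadings")
  }
  if (!is.null(raw$loading)) from_plain(raw) else lapply(raw, from_plain)
}

#' @export
print.mets_loadings <- function(x, ...) {
  cat("<mets_loadings> subgroup:", x$subgroup,
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(round(x$loading, 3))
  invisible(x)
}
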