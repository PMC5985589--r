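#' Declare one longitudinal marker submodel
#'
#' A marker is one longitudinal outcome (e.g. a seizure indicator, a
#' log-transformed seizure count, an adverse-event count) modelled by a
#' generalized linear mixed submodel with its canonical link.  The
#' random part always contains an implicit leading random intercept;
#' `random` lists any further random-effect covariates.  The fixed part
#' has no intercept — the random intercept's (free) mixture mean is the
#' marker's level, and a fixed intercept would not be identified beside
#' it — so `fixed` lists exactly the fixed-effect covariates used.
#'
#' Two covariate names are derived from the marker's own visit grid and
#' need not be present in the data: `"time_since_diagnosis"` (the visit
#' time itself, days) and `"time_since_last_visit"` (gap to the previous
#' visit of this marker; at the first visit it equals the time since
#' diagnosis).  All other names are looked up among the subject's
#' per-visit covariates and then among the baseline covariates.
#'
#' @param name marker identifier (matching the `marker` column of the
#'   long data table).
#' @param family one of `"gaussian"`, `"bernoulli"`, `"poisson"`; the
#'   link is the canonical one (identity, logit, log respectively).
#' @param fixed character vector of fixed-effect covariate names
#'   (intercept implicit, not listed).
#' @param random character vector of random-effect covariate names
#'   (default: random intercept only).
#' @param transform optional value transform applied when loading data;
#'   currently `"log1p"` (i.e. \eqn{\log(1+y)}) or `NULL`.
#' @return an object of class `marker_spec`.
#' @export
marker_spec <- function(name, family = c("gaussian", "bernoulli", "poisson"),
                        fixed = character(), random = character(),
                        transform = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(transform) && !identical(transform, "log1p"))
    stop("unsupported transform: ", transform)
  if (anyDuplicated(fixed) || anyDuplicated(random))
    stop("duplicated covariate names in marker '", name, "'")
  structure(
    list(name = name, family = family,
         link = switch(family, gaussian = "identity",
                       bernoulli = "logit", poisson = "log"),
         fixed = as.character(fixed), random = as.character(random),
         transform = transform),
    class = "marker_spec")
}

#' Weakly informative prior settings for one group model
#'
#' Defaults follow the package's weakly-informative concretization:
#' independent N(0, `alpha_var`) on each fixed effect, inverse-gamma on
#' gaussian dispersions, symmetric Dirichlet on mixture weights.  The
#' mixture-mean and covariance hyperparameters default to `NULL`, meaning
#' they are derived from crude subject-level intercept estimates
#' (winsorized working-residual means) at fit time: mean prior centred
#' at 0 with variance four times the crude range, inverse-Wishart scale
#' the diagonal of the crude variances with df `q + 1`.  Supply explicit
#' values to override.
#'
#' @param alpha_var prior variance of each fixed effect.
#' @param phi_shape,phi_rate inverse-gamma hyperparameters for gaussian
#'   dispersion (variance) parameters.
#' @param dirichlet symmetric Dirichlet concentration for the weights.
#' @param mu_mean,mu_var optional mixture-mean prior centre (length q)
#'   and variance (q x q matrix or scalar).
#' @param wishart_df,wishart_scale optional inverse-Wishart df and scale.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_var = 1e4, phi_shape = 1, phi_rate = 0.005,
                       dirichlet = 1, mu_mean = NULL, mu_var = NULL,
                       wishart_df = NULL, wishart_scale = NULL) {
  stopifnot(alpha_var > 0, phi_shape > 0, phi_rate > 0, dirichlet > 0)
  structure(list(alpha_var = alpha_var, phi_shape = phi_shape,
                 phi_rate = phi_rate, dirichlet = dirichlet,
                 mu_mean = mu_mean, mu_var = mu_var,
                 wishart_df = wishart_df, wishart_scale = wishart_scale),
            class = "prior_spec")
}

#' Declare the MGLMM for one prognostic group
#'
#' @param group integer group label in `0:(G-1)`.
#' @param markers list of [marker_spec()] objects (same marker names in
#'   every group; covariate sets may differ by group).
#' @param K number of components of the normal mixture assumed for the
#'   random effects in this group.
#' @param prior a [prior_spec()].
#' @return an object of class `group_model_spec`.
#' @export
group_model_spec <- function(group, markers, K = 1L, prior = prior_spec()) {
  stopifnot(length(group) == 1L, group >= 0, K >= 1, length(markers) >= 1L)
  if (!all(vapply(markers, inherits, TRUE, "marker_spec")))
    stop("markers must be a list of marker_spec objects")
  nm <- vapply(markers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("marker names must be unique within a spec")
  names(markers) <- nm
  structure(list(group = as.integer(group), markers = markers,
                 K = as.integer(K), prior = prior),
            class = "group_model_spec")
}

.marker_names <- function(spec) names(spec$markers)

# random-effect dimension and per-marker column offsets implied by a spec
.ranef_layout <- function(spec) {
  q_r <- vapply(spec$markers, function(m) 1L + length(m$random), 1L)
  offsets <- cumsum(c(0L, q_r[-length(q_r)]))
  names(offsets) <- names(q_r)
  list(q = sum(q_r), q_r = q_r, offsets = offsets)
}

#' Construct one subject's longitudinal record
#'
#' @param subject_id identifier.
#' @param group integer group label, or `NA` for a subject to be
#'   classified.
#' @param markers named list; each element a list with numeric `times`
#'   (strictly increasing, days since diagnosis), `values`, and
#'   optionally a data frame `covariates` with one row per visit.
#' @param baseline named list of baseline covariate values.
#' @return an object of class `subject_data`.
#' @export
subject_data <- function(subject_id, group = NA, markers, baseline = list()) {
  for (nm in names(markers)) {
    m <- markers[[nm]]
    tt <- m$times
    if (length(tt) != length(m$values))
      stop("subject ", subject_id, ", marker ", nm,
           ": times and values differ in length")
    if (length(tt) && (any(tt < 0) || any(diff(tt) <= 0)))
      stop("subject ", subject_id, ", marker ", nm,
           ": times must be non-negative and strictly increasing")
    if (!is.null(m$covariates) && nrow(m$covariates) != length(tt))
      stop("subject ", subject_id, ", marker ", nm,
           ": covariate rows must match number of visits")
  }
  structure(list(subject_id = as.character(subject_id),
                 group = if (is.na(group)) NA_integer_ else as.integer(group),
                 markers = markers, baseline = baseline),
            class = "subject_data")
}

#' Restrict a subject's record to the history known by time t
#'
#' Keeps, for every marker separately, the observations with visit time
#' `<= t` (inclusive boundary), together with their covariate rows.  An
#' empty history is legal.
#'
#' @param subject a [subject_data()] object.
#' @param t time in days since diagnosis, `>= 0`.
#' @return a `subject_data` object.
#' @export
truncate_history <- function(subject, t) {
  stopifnot(inherits(subject, "subject_data"), t >= 0)
  subject$markers <- lapply(subject$markers, function(m) {
    keep <- m$times <= t
    m$times <- m$times[keep]
    m$values <- m$values[keep]
    if (!is.null(m$covariates)) m$covariates <- m$covariates[keep, , drop = FALSE]
    m
  })
  subject
}

# resolve one covariate column for a marker's visit grid
.covariate_column <- function(subject, mspec, name) {
  m <- subject$markers[[mspec$name]]
  tt <- m$times
  n <- length(tt)
  if (name == "time_since_diagnosis") return(tt)
  if (name == "time_since_last_visit") {
    if (n == 0L) return(numeric(0))
    return(c(tt[1L], diff(tt)))
  }
  if (!is.null(m$covariates) && name %in% names(m$covariates)) {
    v <- m$covariates[[name]]
    if (anyNA(v))
      stop("subject ", subject$subject_id, ", marker ", mspec$name,
           ", visit ", which(is.na(v))[1L], ": missing value for covariate '",
           name, "'")
    return(as.numeric(v))
  }
  if (name %in% names(subject$baseline)) {
    v <- subject$baseline[[name]]
    if (is.na(v))
      stop("subject ", subject$subject_id, ": missing baseline covariate '",
           name, "'")
    return(rep(as.numeric(v), n))
  }
  stop("subject ", subject$subject_id, ", marker ", mspec$name,
       ": covariate '", name, "' not found")
}

#' Build per-marker fixed and random design matrices for one subject
#'
#' Row `j` of `Z_r` holds the random-effect covariates of the `j`th
#' visit of marker `r`, with an implicit leading 1 for the random
#' intercept; row `j` of `X_r` holds the fixed-effect covariates.  `X_r`
#' carries *no* intercept column: every marker has a random intercept
#' whose mixture mean is free, so a fixed intercept would not be
#' identified (any constant can be shifted between the two), and the
#' marker's overall level is read off the random-intercept mixture mean
#' instead.  Covariate sets are those declared for the requested group,
#' so different groups may use different designs for the same data.
#'
#' @param subject a [subject_data()] object.
#' @param spec the [group_model_spec()] of the group whose design is
#'   wanted.
#' @return named list per marker with matrices `X` (`n_r x p_r`) and `Z`
#'   (`n_r x q_r`).
#' @export
build_design_rows <- function(subject, spec) {
  out <- lapply(spec$markers, function(mspec) {
    m <- subject$markers[[mspec$name]]
    n <- if (is.null(m)) 0L else length(m$times)
    build1 <- function(covs, intercept) {
      M <- matrix(1, nrow = n, ncol = intercept + length(covs))
      colnames(M) <- c(if (intercept) "(Intercept)", covs)
      for (j in seq_along(covs))
        M[, j + intercept] <- .covariate_column(subject, mspec, covs[j])
      M
    }
    list(X = build1(mspec$fixed, 0L), Z = build1(mspec$random, 1L))
  })
  names(out) <- .marker_names(spec)
  out
}

.validate_family_values <- function(values, family, subject_id, marker, times) {
  bad <- switch(family,
    bernoulli = which(!(values %in% c(0, 1))),
    poisson = which(values < 0 | values != floor(values)),
    gaussian = which(!is.finite(values)))
  if (length(bad))
    stop("subject ", subject_id, ", marker ", marker, ", time ",
         times[bad[1L]], ": value ", values[bad[1L]],
         " invalid for family ", family)
  invisible(TRUE)
}

#' Assemble a validated dataset from long-format tables
#'
#' @param long_table long-format observations: a data frame or CSV path
#'   with columns `subject_id`, `marker`, `time`, `value` and optionally
#'   further per-visit covariate columns.
#' @param subject_table subject-level table: data frame or CSV path with
#'   `subject_id`, `group` (may be `NA` for unlabelled subjects) and one
#'   column per baseline covariate.
#' @param specs list of [group_model_spec()] (one per group); marker
#'   declarations and transforms are taken from the first.
#' @return an object of class `loda_dataset`: list with `subjects` (a
#'   named list of [subject_data()]) and `covariates` (names seen).
#'   Rows whose marker is not declared in the spec are dropped and
#'   reported via attribute `"rejected"`.
#' @export
load_dataset <- function(long_table, subject_table, specs) {
  long <- if (is.character(long_table))
    utils::read.csv(long_table, stringsAsFactors = FALSE) else as.data.frame(long_table)
  subj <- if (is.character(subject_table))
    utils::read.csv(subject_table, stringsAsFactors = FALSE) else as.data.frame(subject_table)
  need <- c("subject_id", "marker", "time", "value")
  if (!all(need %in% names(long)))
    stop("long table must have columns ", paste(need, collapse = ", "))
  if (!"subject_id" %in% names(subj))
    stop("subject table must have a subject_id column")
  spec1 <- specs[[1L]]
  known <- .marker_names(spec1)

  rejected <- long[!(long$marker %in% known), , drop = FALSE]
  long <- long[long$marker %in% known, , drop = FALSE]

  key <- paste(long$subject_id, long$marker, long$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), ][1L, ]
    stop("duplicate observation: subject ", d$subject_id, ", marker ",
         d$marker, ", time ", d$time)
  }

  covnames <- setdiff(names(long), need)
  base_names <- setdiff(names(subj), c("subject_id", "group"))
  subjects <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    sid <- as.character(subj$subject_id[i])
    rows <- long[long$subject_id == sid, , drop = FALSE]
    markers <- list()
    for (mspec in spec1$markers) {
      mr <- rows[rows$marker == mspec$name, , drop = FALSE]
      mr <- mr[order(mr$time), , drop = FALSE]
      vals <- mr$value
      if (!is.null(mspec$transform) && mspec$transform == "log1p")
        vals <- log1p(vals)
      .validate_family_values(vals, mspec$family, sid, mspec$name, mr$time)
      markers[[mspec$name]] <- list(
        times = mr$time, values = vals,
        covariates = if (length(covnames))
          mr[, covnames, drop = FALSE] else NULL)
    }
    grp <- if ("group" %in% names(subj)) subj$group[i] else NA
    baseline <- as.list(subj[i, base_names, drop = FALSE])
    subjects[[i]] <- subject_data(sid, group = if (is.na(grp)) NA else grp,
                                  markers = markers, baseline = baseline)
  }
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("subject_ids must be unique")
  names(subjects) <- ids
  out <- structure(list(subjects = subjects,
                        covariates = union(covnames, base_names)),
                   class = "loda_dataset")
  if (nrow(rejected)) {
    warning(nrow(rejected), " rows with undeclared markers dropped: ",
            paste(unique(rejected$marker), collapse = ", "))
    attr(out, "rejected") <- rejected
  }
  out
}

#' @export
print.loda_dataset <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, 1L, "group")
  cat("<loda_dataset> ", length(x$subjects), " subjects; group counts: ",
      paste(sprintf("%s=%d", names(table(groups, useNA = "ifany")),
                    table(groups, useNA = "ifany")), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# subjects of one group as a plain list
.group_subjects <- function(dataset, g) {
  Filter(function(s) !is.na(s$group) && s$group == g, dataset$subjects)
}
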