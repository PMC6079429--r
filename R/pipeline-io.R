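# Preprocessing, discovery -> validation workflow with bootstrap, and
# plain-text file I/O.

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# Profile log-likelihood of the Box-Cox lambda over all pooled entries:
# ll(lambda) = -N/2 log(sigma2_mle(z)) + (lambda - 1) sum(log y).
boxcox_profile_loglik <- function(lambda, y, sumlog) {
  z <- boxcox_transform(y, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  -length(y) / 2 * log(s2) + (lambda - 1) * sumlog
}

#' Box-Cox transformation plus per-probe standardization
#'
#' Applies one shared Box-Cox power transform to every entry of the matrix
#' (a shift of `1 - min` is applied first if any entry is non-positive),
#' with the power chosen by profile maximum likelihood over all pooled
#' entries, then centers and scales every probe row so its mean is 0 and
#' its sample variance is 1. Rows that are constant after the transform
#' are dropped with a warning.
#'
#' @param data A raw [expression_dataset()].
#' @param lambda Optional fixed Box-Cox power; by default estimated by
#'   profile maximum likelihood over `[-3, 3]`.
#'
#' @return A list with `data` (the preprocessed dataset) and `record`
#'   (class `PreprocessRecord`: `boxcox_lambda`, `shift`,
#'   `per_probe_center`, `per_probe_scale`, `dropped`).
#' @export
preprocess <- function(data, lambda = NULL) {
  x <- data$values
  shift <- if (any(x <= 0)) 1 - min(x) else 0
  y <- x + shift
  if (is.null(lambda)) {
    sumlog <- sum(log(y))
    lambda <- stats::optimize(boxcox_profile_loglik, c(-3, 3), y = as.vector(y),
                              sumlog = sumlog, maximum = TRUE)$maximum
  }
  z <- boxcox_transform(y, lambda)
  ctr <- rowMeans(z)
  scl <- sqrt(apply(z, 1, stats::var))
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " constant probe row(s) dropped after transform: ",
            paste(utils::head(data$probe_ids[!keep], 5), collapse = ", "))
  z <- (z - ctr) / scl
  out <- expression_dataset(z[keep, , drop = FALSE], as.character(data$group),
                            data$probe_ids[keep])
  colnames(out$values) <- colnames(data$values)
  record <- structure(
    list(boxcox_lambda = lambda, shift = shift,
         per_probe_center = ctr[keep], per_probe_scale = scl[keep],
         dropped = data$probe_ids[!keep]),
    class = "PreprocessRecord"
  )
  list(data = out, record = record)
}

# Row re-standardization only (used per bootstrap replicate; the Box-Cox
# power is not re-estimated).
rescale_rows <- function(data) {
  z <- data$values
  ctr <- rowMeans(z)
  scl <- sqrt(apply(z, 1, stats::var))
  keep <- scl > 0
  z <- (z[keep, , drop = FALSE] - ctr[keep]) / scl[keep]
  out <- expression_dataset(z, as.character(data$group),
                            data$probe_ids[keep])
  colnames(out$values) <- colnames(data$values)
  out
}

#' Validate discovery DV calls against an independent validation cohort
#'
#' A discovery DV probe counts as validated when it is DV in the validation
#' dataset too and the sign of the sample-variance difference
#' \eqn{s_c^2 - s_n^2} agrees between the two datasets. The validation
#' rate is `pValid = n12 / n1` where `n1` is the discovery DV count and
#' `n12` the validated count. Probes are matched by id; the intersection is
#' used and mismatches are reported.
#'
#' @param discovery,validation `dv_calls` data frames (from [detect_dv()] or
#'   [probewise_detect()]).
#'
#' @return A `ValidationResult` list: `n1`, `n12`, `pValid`, and a
#'   `per_probe` data frame with flags and signs from both cohorts.
#' @export
validate_dv <- function(discovery, validation) {
  common <- intersect(discovery$probe_id, validation$probe_id)
  n_miss <- length(discovery$probe_id) + length(validation$probe_id) -
    2L * length(common)
  if (n_miss > 0L)
    message(n_miss, " probe id(s) absent from one of the two call sets; ",
            "using the intersection of ", length(common))
  d <- discovery[match(common, discovery$probe_id), ]
  v <- validation[match(common, validation$probe_id), ]
  validated <- d$dv & v$dv & d$direction == v$direction & d$direction != 0
  n1 <- sum(d$dv)
  n12 <- sum(validated)
  if (n1 == 0L) warning("no DV probes in the discovery set; pValid undefined")
  structure(
    list(n1 = n1, n12 = n12, pValid = if (n1 == 0L) NaN else n12 / n1,
         per_probe = data.frame(
           probe_id = common,
           dv_discovery = d$dv, dv_validation = v$dv,
           sign_discovery = d$direction, sign_validation = v$direction,
           validated = validated,
           row.names = NULL, stringsAsFactors = FALSE)),
    class = "ValidationResult"
  )
}

make_detector <- function(method, config, alpha) {
  if (method == "gs") {
    function(data) detect_dv(data, config)
  } else {
    method <- match.arg(method, PROBEWISE_TESTS)
    function(data) probewise_detect(data, method, alpha)
  }
}

resample_within_groups <- function(data) {
  idx <- group_index(data)
  take <- c(sample(idx$case, length(idx$case), replace = TRUE),
            sample(idx$control, length(idx$control), replace = TRUE))
  out <- expression_dataset(data$values[, take, drop = FALSE],
                            as.character(data$group)[take],
                            data$probe_ids)
  colnames(out$values) <- colnames(data$values)[take]
  out
}

#' Bootstrap distribution of the validation rate
#'
#' Resamples subjects with replacement within each group, independently in
#' the discovery and validation datasets, re-standardizes probe rows, reruns
#' the chosen detector on both cohorts, and records the validation rate
#' `pValid` for each replicate. Inputs are expected to be already
#' preprocessed (the Box-Cox power is not re-estimated per replicate).
#'
#' @param discovery,validation Preprocessed [expression_dataset()]s sharing
#'   probe ids.
#' @param method `"gs"` or one of the probe-wise tests
#'   (`"F"`, `"levene"`, `"bf"`, `"ltrim"`).
#' @param B Number of bootstrap replicates.
#' @param seed Random seed for the resampling stream.
#' @param config [fit_config()] used when `method = "gs"`.
#' @param alpha FDR threshold for probe-wise methods.
#' @param resample Test hook; `FALSE` skips resampling so every replicate
#'   reproduces the plain validation rate.
#'
#' @return Numeric vector of B validation rates (NaN for replicates with no
#'   discovery DV probes).
#' @export
bootstrap_validation_rates <- function(discovery, validation, method = "gs",
                                       B = 100L, seed = 1L,
                                       config = fit_config(seed = seed),
                                       alpha = 0.05, resample = TRUE) {
  stopifnot(B >= 1L)
  detector <- make_detector(method, config, alpha)
  set.seed(seed)
  vapply(seq_len(B), function(b) {
    d <- discovery
    v <- validation
    if (resample) {
      d <- resample_within_groups(d)
      v <- resample_within_groups(v)
    }
    res <- suppressWarnings(
      validate_dv(detector(rescale_rows(d)), detector(rescale_rows(v))))
    res$pValid
  }, numeric(1))
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix with group labels
#'
#' Expects probe ids in the first column and sample ids in the header.
#' Group labels come either from a two-column annotation file
#' (`sample_id`, `group`) or from the sample-id prefix convention
#' `case_*` / `control_*`. The delimiter is inferred from the extension
#' (`.csv` comma, otherwise tab).
#'
#' @param path Path to the TSV/CSV matrix.
#' @param annotation Optional path to the sample annotation file.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, annotation = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  probe_ids <- as.character(df[[1]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  mat <- df[, -1, drop = FALSE]
  nonnum <- !vapply(mat, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric expression column(s) in ", path, ": ",
         paste(names(mat)[nonnum], collapse = ", "))
  mat <- as.matrix(mat)
  sample_ids <- colnames(mat)
  if (!is.null(annotation)) {
    ann <- utils::read.table(annotation, header = TRUE,
                             sep = infer_sep(annotation),
                             check.names = FALSE, stringsAsFactors = FALSE)
    grp <- ann[[2]][match(sample_ids, ann[[1]])]
    if (any(is.na(grp)))
      stop("sample id(s) missing from annotation: ",
           paste(sample_ids[is.na(grp)], collapse = ", "))
  } else {
    grp <- sub("_.*$", "", sample_ids)
    bad <- !grp %in% c("case", "control")
    if (any(bad))
      stop("cannot infer group for sample id(s): ",
           paste(sample_ids[bad], collapse = ", "),
           " (use case_*/control_* names or an annotation file)")
  }
  out <- expression_dataset(mat, grp, probe_ids)
  colnames(out$values) <- sample_ids
  out
}

#' Write an expression dataset as TSV/CSV
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces the doubles exactly.
#'
#' @param data An [expression_dataset()].
#' @param path Output path; the delimiter follows the extension.
#'
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  ids <- colnames(data$values)
  if (is.null(ids)) {
    ids <- character(ncol(data$values))
    for (g in c("case", "control")) {
      w <- which(data$group == g)
      ids[w] <- paste0(g, "_", seq_along(w))
    }
  }
  m <- matrix(formatC(data$values, digits = 17, format = "g"),
              nrow = nrow(data$values), dimnames = list(NULL, ids))
  df <- data.frame(probe_id = data$probe_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read simulation truth labels
#'
#' Two-column table (`probe_id`, `label`).
#'
#' @param truth A `SimulationTruth` (or any OV/EV/UV label vector) plus the
#'   matching probe ids.
#' @param probe_ids Probe identifiers aligned with the labels.
#' @param path File path.
#'
#' @return `path` invisibly for the writer; a named factor for the reader.
#' @export
write_truth <- function(truth, probe_ids, path) {
  labels <- if (inherits(truth, "SimulationTruth")) truth$labels else truth
  utils::write.table(
    data.frame(probe_id = probe_ids, label = as.character(labels)),
    path, sep = infer_sep(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  stats::setNames(factor(df$label, levels = CLUSTER_KINDS), df$probe_id)
}

#' Write per-probe detection calls as TSV/CSV
#'
#' @param calls A `dv_calls` data frame.
#' @param path File path.
#'
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = infer_sep(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
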