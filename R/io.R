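#' Construct a longitudinal expression set
#'
#' The raw object of a longitudinal expression study: a genes x subjects x
#' time points array of log-scale expression values (missing cells are `NA`)
#' together with per-subject metadata carrying the binary response label and
#' an optional treatment arm.
#'
#' @param values numeric 3-d array, dim = (genes, subjects, timepoints),
#'   with dimnames giving gene ids, subject ids and time-point labels.
#'   Missing cells are `NA`; everything else must be finite.
#' @param sample_meta data.frame with columns `subject`, `response`
#'   (values "responder"/"non-responder") and optionally `treatment`,
#'   one row per subject.
#' @return an object of class `longexpr_set` with fields `values`,
#'   `gene_ids`, `subject_ids`, `timepoint_labels`, `sample_meta`.
#' @export
longexpr_set <- function(values, sample_meta) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop("values must carry full dimnames (gene, subject, timepoint)")
  obj <- structure(
    list(values = values,
         gene_ids = dn[[1]],
         subject_ids = dn[[2]],
         timepoint_labels = dn[[3]],
         sample_meta = sample_meta),
    class = "longexpr_set")
  validate_longexpr(obj)
}

#' Validate a longitudinal expression set
#'
#' Checks the container invariants: unique gene/subject ids, ordered unique
#' time-point labels, cells finite-or-missing, metadata covering every
#' subject with a recognizable response label.
#'
#' @param x a `longexpr_set`.
#' @return `x`, invisibly modified to canonical response labels.
#' @export
validate_longexpr <- function(x) {
  stopifnot(inherits(x, "longexpr_set"))
  if (anyDuplicated(x$gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(x$subject_ids)) stop("duplicate subject ids")
  if (anyDuplicated(x$timepoint_labels)) stop("duplicate timepoint labels")
  v <- x$values
  if (any(!is.na(v) & !is.finite(v)))
    stop("expression cells must be finite or missing (NA)")
  m <- x$sample_meta
  if (!all(c("subject", "response") %in% names(m)))
    stop("sample_meta needs columns 'subject' and 'response'")
  if (!all(x$subject_ids %in% m$subject))
    stop("every subject needs a metadata row with a response label")
  m <- m[match(x$subject_ids, m$subject), , drop = FALSE]
  m$response <- canon_response(m$response)
  rownames(m) <- NULL
  x$sample_meta <- m
  x
}

#' @exportS3Method base::print
print.longexpr_set <- function(x, ...) {
  cat("Longitudinal expression set:",
      length(x$gene_ids), "genes x",
      length(x$subject_ids), "subjects x",
      length(x$timepoint_labels), "timepoints\n")
  cat("  timepoints:", paste(x$timepoint_labels, collapse = ", "), "\n")
  tab <- table(x$sample_meta$response)
  cat("  response:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' Read a longitudinal expression matrix from TSV
#'
#' Two layouts are supported. `wide`: one row per gene, first column the
#' gene id, remaining columns keyed `subject<sep>timepoint`. `long`: columns
#' `gene`, `subject`, `timepoint`, `value`. Cells that fail to parse as
#' numbers become missing and are tallied in the load report
#' (`attr(x, "load_report")`).
#'
#' @param path TSV file path.
#' @param meta sample metadata: a data.frame or a path readable by
#'   [read_metadata()].
#' @param layout `"wide"` or `"long"`.
#' @param sep separator splitting wide column names into subject and
#'   timepoint (default `"__"`).
#' @param timepoint_order optional explicit ordering of time-point labels;
#'   default is order of first appearance.
#' @return a validated [longexpr_set()] with a `load_report` attribute.
#' @export
read_expression <- function(path, meta, layout = c("wide", "long"),
                            sep = "__", timepoint_order = NULL) {
  layout <- match.arg(layout)
  if (is.character(meta)) meta <- read_metadata(meta)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (layout == "wide") {
    gene <- raw[[1]]
    cols <- names(raw)[-1]
    parts <- strsplit(cols, sep, fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("wide column names must be subject", sep, "timepoint; offender: ",
           cols[which(lengths(parts) != 2)[1]])
    subj <- vapply(parts, `[[`, "", 1)
    tp <- vapply(parts, `[[`, "", 2)
    long <- data.frame(
      gene = rep(gene, times = length(cols)),
      subject = rep(subj, each = length(gene)),
      timepoint = rep(tp, each = length(gene)),
      value = unlist(raw[-1], use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    need <- c("gene", "subject", "timepoint", "value")
    if (!all(need %in% names(raw)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    long <- raw[need]
  }
  key <- paste(long$gene, long$subject, long$timepoint, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup)
    stop("duplicate (gene, subject, timepoint) triple: (",
         long$gene[dup], ", ", long$subject[dup], ", ",
         long$timepoint[dup], ")")
  num <- suppressWarnings(as.numeric(long$value))
  unparseable <- sum(!is.na(long$value) & is.na(num))

  genes <- unique(long$gene)
  subjects <- unique(long$subject)
  tps <- timepoint_order %||% unique(long$timepoint)
  if (!all(long$timepoint %in% tps))
    stop("timepoint label not covered by timepoint_order")
  if (!any(subjects %in% meta$subject))
    stop("no overlap between matrix subjects and metadata subjects")
  subjects <- subjects[subjects %in% meta$subject]
  keep <- long$subject %in% subjects

  values <- array(NA_real_, dim = c(length(genes), length(subjects), length(tps)),
                  dimnames = list(genes, subjects, tps))
  idx <- cbind(match(long$gene[keep], genes),
               match(long$subject[keep], subjects),
               match(long$timepoint[keep], tps))
  values[idx] <- num[keep]

  out <- longexpr_set(values, meta)
  attr(out, "load_report") <- list(
    n_cells = length(values),
    n_missing = sum(is.na(values)),
    n_unparseable = unparseable,
    n_subjects_dropped = length(unique(long$subject)) - length(subjects))
  out
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `subject`, `response`, optional `treatment`.
#' @return data.frame with canonical response labels.
#' @export
read_metadata <- function(path) {
  m <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  colClasses = "character")
  if (!all(c("subject", "response") %in% names(m)))
    stop("metadata needs columns 'subject' and 'response'")
  if (anyDuplicated(m$subject))
    stop("duplicate subject in metadata: ",
         m$subject[anyDuplicated(m$subject)])
  m$response <- canon_response(m$response)
  m
}

#' Write a longitudinal expression set to TSV
#'
#' Inverse of [read_expression()]; missing cells serialize as `NA`.
#'
#' @param x a `longexpr_set`.
#' @param path output TSV path.
#' @param layout `"wide"` or `"long"`.
#' @param sep wide-layout column key separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, layout = c("wide", "long"),
                             sep = "__") {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "longexpr_set"))
  if (layout == "wide") {
    mats <- lapply(seq_along(x$timepoint_labels), function(k) {
      m <- x$values[, , k, drop = FALSE]
      dim(m) <- dim(x$values)[1:2]
      colnames(m) <- paste(x$subject_ids, x$timepoint_labels[k], sep = sep)
      m
    })
    wide <- do.call(cbind, mats)
    df <- data.frame(gene = x$gene_ids, wide, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- expand.grid(gene = x$gene_ids, subject = x$subject_ids,
                     timepoint = x$timepoint_labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$value <- as.vector(x$values)
    write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a sample metadata table
#'
#' @param meta data.frame as held in `sample_meta`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the multi-view representation of a longitudinal set
#'
#' Each requested time point becomes one view: a genes x subjects matrix.
#' Subjects missing any cell at a used time point are dropped so all views
#' stay aligned (missingness at unused time points is ignored). With
#' `standardize = TRUE` (default) every gene row within every view is
#' z-scored across the retained subjects; zero-variance rows are centered
#' and left at zero, and flagged.
#'
#' @param data a `longexpr_set`.
#' @param use_timepoints ordered character vector of time-point labels.
#' @param standardize logical; z-score gene rows per view.
#' @return an object of class `view_stack`: list with `views` (list of
#'   matrices), `view_labels`, `gene_ids`, `subject_ids`, `labels`
#'   (response per retained subject), `standardized`,
#'   `standardization` (per-view centers/scales), `zero_variance`
#'   (per-view logical matrix rows flag).
#' @export
build_views <- function(data, use_timepoints, standardize = TRUE) {
  stopifnot(inherits(data, "longexpr_set"))
  unknown <- setdiff(use_timepoints, data$timepoint_labels)
  if (length(unknown))
    stop("unknown timepoint label(s): ", paste(unknown, collapse = ", "))
  if (!length(use_timepoints)) stop("use_timepoints must be non-empty")

  sub <- data$values[, , use_timepoints, drop = FALSE]
  complete <- apply(!is.na(sub), 2, all)
  subjects <- data$subject_ids[complete]
  if (!length(subjects))
    stop("all subjects dropped: every subject has a missing cell at a used timepoint")
  if (length(subjects) < 4)
    stop("fewer than 4 subjects remain after dropping incomplete subjects")

  meta <- data$sample_meta[match(subjects, data$sample_meta$subject), ,
                           drop = FALSE]
  views <- vector("list", length(use_timepoints))
  std <- vector("list", length(use_timepoints))
  zv <- vector("list", length(use_timepoints))
  for (k in seq_along(use_timepoints)) {
    m <- sub[, complete, k, drop = FALSE]
    dim(m) <- c(dim(sub)[1], length(subjects))
    dimnames(m) <- list(data$gene_ids, subjects)
    if (standardize) {
      ctr <- rowMeans(m)
      scl <- apply(m, 1, sd)
      flag <- scl < 1e-12
      scl[flag] <- 1
      m <- (m - ctr) / scl
      std[[k]] <- list(center = ctr, scale = scl)
      zv[[k]] <- flag
    } else {
      std[[k]] <- NULL
      zv[[k]] <- rep(FALSE, nrow(m))
    }
    views[[k]] <- m
  }
  structure(list(views = views,
                 view_labels = use_timepoints,
                 gene_ids = data$gene_ids,
                 subject_ids = subjects,
                 labels = setNames(meta$response, subjects),
                 standardized = standardize,
                 standardization = std,
                 zero_variance = zv),
            class = "view_stack")
}

#' @exportS3Method base::print
print.view_stack <- function(x, ...) {
  cat("View stack: T =", length(x$views), "views (",
      paste(x$view_labels, collapse = ", "), ")\n")
  cat("  ", length(x$gene_ids), "genes x", length(x$subject_ids),
      "subjects; standardized:", x$standardized, "\n")
  invisible(x)
}

# row-stack the views into the single (p_total x n) matrix the factor model
# consumes; conditional independence given Z makes this identical to
# per-view models sharing Z
stack_views <- function(views) {
  if (inherits(views, "view_stack")) views <- views$views
  stopifnot(is.list(views), length(views) >= 1)
  dims <- vapply(views, dim, integer(2))
  if (length(unique(dims[2, ])) != 1)
    stop("views must share the subject dimension")
  do.call(rbind, views)
}

# restrict every view of a stack to a gene subset, preserving alignment
subset_genes <- function(views, gene_indices) {
  stopifnot(inherits(views, "view_stack"))
  out <- views
  out$views <- lapply(views$views, function(m) m[gene_indices, , drop = FALSE])
  out$gene_ids <- views$gene_ids[gene_indices]
  out$zero_variance <- lapply(views$zero_variance,
                              function(z) z[gene_indices])
  out
}

#' Serialize a result object to disk
#'
#' Deterministic serialization: JSON reports are written with sorted keys
#' and full numeric precision so identical results yield byte-identical
#' files. Ensemble and evaluation results, trajectory summaries and plain
#' lists are supported; evaluation results may alternatively be written as
#' a per-fold TSV.
#'
#' @param obj result object (e.g. `icluster_ensemble`,
#'   `evaluation_result`, `trajectory_summary`, or a named list).
#' @param path output path.
#' @param format `"json"` or `"tsv"` (tsv applies to evaluation results and
#'   trajectory summaries).
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- if (inherits(obj, "evaluation_result")) {
      data.frame(subject = names(obj$fold_predictions),
                 predicted = unname(obj$fold_predictions),
                 truth = unname(obj$truth),
                 stringsAsFactors = FALSE)
    } else if (inherits(obj, "trajectory_summary")) {
      as.data.frame(obj)
    } else stop("tsv format supports evaluation results and trajectory summaries")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  payload <- report_payload(obj)
  jsonlite::write_json(sort_keys(payload), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

report_payload <- function(obj) UseMethod("report_payload")

#' @export
report_payload.default <- function(obj) {
  if (is.list(obj)) return(obj)
  stop("no report serialization for class ", paste(class(obj), collapse = "/"))
}

#' @export
report_payload.icluster_ensemble <- function(obj) {
  # descending score, lexicographic ids within ties
  ord <- order(-obj$gene_scores, names(obj$gene_scores), method = "radix")
  sc <- obj$gene_scores[ord]
  list(type = "ensemble_result",
       n_replicates = obj$n_replicates,
       subset_size = obj$subset_size,
       accuracy_cutoff = obj$accuracy_cutoff,
       kept_count = obj$kept_count,
       vote_accuracy = obj$vote_accuracy,
       seed = obj$seed,
       gene_scores = as.list(sc),
       times_sampled = as.list(obj$times_sampled),
       times_kept = as.list(obj$times_kept),
       voted_labels = as.list(obj$voted_labels),
       vote_counts = list(subject = rownames(obj$vote_counts),
                          responder = unname(obj$vote_counts[, RESPONDER]),
                          `non-responder` = unname(obj$vote_counts[, NONRESPONDER])))
}

#' @export
report_payload.evaluation_result <- function(obj) {
  list(type = "evaluation_result",
       accuracy = obj$accuracy,
       confusion = as.list(as.data.frame.matrix(obj$confusion)),
       fold_predictions = as.list(obj$fold_predictions),
       truth = as.list(obj$truth),
       svm_params = obj$svm_params,
       seed = obj$seed %||% NA)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return a named list mirroring the serialized payload.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
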