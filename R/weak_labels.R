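## Threshold labeling functions, label-matrix construction, diagnostics.
##
## Each labeling function (LF) watches one sex-normalized primitive and votes
## {-1 = TAV, 0 = abstain, +1 = BAV} by thresholds: values at or below `low`
## emit `low_vote`, values at or above `high` emit `high_vote`, anything in
## between (or with an undefined input primitive) abstains. LF votes are
## collected over a window of t frames centered on the peak-flow frame.

#' Construct a threshold labeling function
#'
#' @param name LF name.
#' @param feature The primitive the thresholds apply to (one of `area`,
#'   `perimeter`, `eccentricity`, `intensity`, `ratio`).
#' @param input_primitives Character vector of primitives the LF depends on;
#'   defaults to `feature`, but derived features may declare several (e.g.,
#'   `ratio` depends on `area` and `perimeter`), which drives dependency
#'   inference in the label model.
#' @param low,high Thresholds in normalized units (`NA` disables that side).
#' @param low_vote,high_vote Votes in {-1, 0, 1} emitted at each side.
#' @return Object of class `labeling_function` with a derived `polarity`
#'   field (`"both"`, `"positive"`, or `"negative"`).
#' @export
labeling_function <- function(name, feature, input_primitives = feature,
                              low = NA, high = NA,
                              low_vote = 0L, high_vote = 0L) {
  stopifnot(feature %in% PRIMITIVE_NAMES,
            all(input_primitives %in% PRIMITIVE_NAMES),
            low_vote %in% -1:1, high_vote %in% -1:1)
  if (!is.na(low) && !is.finite(low)) stop("low threshold must be finite")
  if (!is.na(high) && !is.finite(high)) stop("high threshold must be finite")
  votes <- setdiff(unique(c(if (!is.na(low)) low_vote,
                            if (!is.na(high)) high_vote)), 0L)
  polarity <- if (all(c(-1L, 1L) %in% votes)) "both"
              else if (1L %in% votes) "positive" else "negative"
  structure(list(name = name, feature = feature,
                 input_primitives = input_primitives,
                 low = low, high = high,
                 low_vote = as.integer(low_vote),
                 high_vote = as.integer(high_vote),
                 polarity = polarity),
            class = "labeling_function")
}

#' The five default labeling functions
#'
#' LF_Area, LF_Perimeter, LF_Eccentricity, LF_Intensity, and LF_Ratio, with
#' thresholds read from a config (default: the packaged YAML, whose values
#' were calibrated from distributional statistics of a seeded phantom
#' development cohort). LF_Perimeter is positive-leaning (high perimeter ->
#' BAV) and LF_Intensity negative-leaning (high mean flow intensity -> TAV).
#'
#' @param config Either a path to a YAML config, a parsed config list, or
#'   `NULL` for the packaged defaults.
#' @return List of 5 [labeling_function()] objects, named.
#' @export
make_default_lfs <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "default_lf_config.yaml",
                          package = "valveweak")
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  defs <- config$labeling_functions
  lfs <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    labeling_function(
      name = nm, feature = d$feature,
      input_primitives = unlist(d$input_primitives %||% d$feature),
      low = d$low %||% NA, high = d$high %||% NA,
      low_vote = d$low_vote %||% 0L, high_vote = d$high_vote %||% 0L)
  })
  names(lfs) <- names(defs)
  lfs
}

## Evaluate one LF on a normalized primitive table -> votes in {-1,0,1}.
eval_lf <- function(lf, records) {
  v <- records[[lf$feature]]
  defined <- rep(TRUE, nrow(records))
  for (p in lf$input_primitives) {
    defined <- defined & records[[paste0("defined_", p)]]
  }
  vote <- integer(nrow(records))
  ok <- defined & !is.na(v)
  if (!is.na(lf$low)) vote[ok & v <= lf$low] <- lf$low_vote
  if (!is.na(lf$high)) vote[ok & v >= lf$high] <- lf$high_vote
  vote
}

#' Apply labeling functions over peak-centered frame windows
#'
#' Votes are computed on the frames `peak - t/2 ... peak + t/2` (inclusive on
#' both ends, so an even `t` yields `t + 1` frames) for each patient; rows
#' are ordered by (patient, frame). Window frames missing from the primitive
#' table are clipped with a warning.
#'
#' @param records A normalized primitive table ([normalize_primitives()]).
#' @param lfs List of [labeling_function()]s.
#' @param peaks Named vector (patient_id -> 0-based peak frame).
#' @param t Window parameter (default 6, the best-performing label-window
#'   size).
#' @return A `label_matrix`: integer matrix (rows = patient-frames, columns
#'   = LFs) with attributes `frame_map` (data.frame patient_id, frame_index)
#'   and `lf_names`.
#' @export
apply_lfs <- function(records, lfs, peaks, t = 6) {
  hw <- floor(t / 2)
  ids <- unique(records$patient_id)
  missing_pk <- setdiff(ids, names(peaks))
  if (length(missing_pk)) stop("no peak frame for patient(s): ",
                               paste(missing_pk, collapse = ", "))
  keep <- abs(records$frame_index - peaks[records$patient_id]) <= hw
  win <- records[keep, , drop = FALSE]
  win <- win[order(win$patient_id, win$frame_index), , drop = FALSE]
  got <- table(win$patient_id)
  if (any(got < 2 * hw + 1)) {
    warning(sprintf("labeling window clipped for %d patient(s)",
                    sum(got < 2 * hw + 1)))
  }
  L <- vapply(lfs, eval_lf, integer(nrow(win)), records = win)
  L <- matrix(as.integer(L), nrow(win), length(lfs),
              dimnames = list(NULL, vapply(lfs, `[[`, "", "name")))
  attr(L, "frame_map") <- data.frame(patient_id = win$patient_id,
                                     frame_index = win$frame_index,
                                     stringsAsFactors = FALSE)
  attr(L, "lf_names") <- colnames(L)
  class(L) <- c("label_matrix", class(L))
  L
}

#' Labeling-function coverage
#'
#' Fraction of rows on which the LF votes -1 or +1.
#'
#' @param L A label matrix.
#' @param j LF index or name; `NULL` for all columns.
#' @return Numeric coverage(s) in [0, 1].
#' @export
lf_coverage <- function(L, j = NULL) {
  if (is.null(j)) colMeans(L != 0) else mean(L[, j] != 0)
}

#' Labeling-function conflict
#'
#' Fraction of rows where the LF votes non-abstain and at least one other LF
#' votes non-abstain with a different value. A single-LF matrix has conflict
#' 0 by convention.
#'
#' @inheritParams lf_coverage
#' @return Numeric conflict(s) in [0, 1].
#' @export
lf_conflict <- function(L, j = NULL) {
  one <- function(jj) {
    if (ncol(L) < 2) return(0)
    v <- L[, jj]
    disag <- rowSums(L != 0 & L != v) > 0
    mean(v != 0 & disag)
  }
  if (is.null(j)) {
    out <- vapply(seq_len(ncol(L)), one, numeric(1))
    names(out) <- colnames(L)
    out
  } else one(j)
}

#' Per-LF performance against gold frame labels
#'
#' Precision, recall, and F1 are computed with abstains counted as TAV (-1)
#' votes, reflecting the strong prior on the negative class; positive and
#' negative accuracy are computed on non-abstain votes split by gold class.
#' All metrics are on the 0-100 display scale.
#'
#' @param L A label matrix.
#' @param gold Vector in {-1, 1} aligned with the rows of `L`.
#' @return data.frame, one row per LF: coverage, conflict, pos_acc, neg_acc,
#'   precision, recall, f1.
#' @export
lf_gold_metrics <- function(L, gold) {
  if (length(gold) != nrow(L)) stop("gold labels must align with rows of L",
                                    call. = FALSE)
  if (length(gold) == 0) stop("empty gold labels", call. = FALSE)
  rows <- lapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]
    nz <- v != 0
    pos_acc <- if (any(nz & gold == 1)) 100 * mean(v[nz & gold == 1] == 1)
               else 0
    neg_acc <- if (any(nz & gold == -1)) 100 * mean(v[nz & gold == -1] == -1)
               else 0
    eff <- ifelse(v == 0, -1L, v)     # abstain -> TAV
    tp <- sum(eff == 1 & gold == 1)
    fp <- sum(eff == 1 & gold == -1)
    fn <- sum(eff == -1 & gold == 1)
    prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(lf = colnames(L)[j],
               coverage = 100 * lf_coverage(L, j),
               conflict = 100 * lf_conflict(L, j),
               pos_acc = pos_acc, neg_acc = neg_acc,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write/read a label matrix as CSV
#'
#' Rows carry patient_id and frame_index; LF columns hold votes in
#' {-1, 0, 1}.
#'
#' @param L A label matrix.
#' @param path CSV path.
#' @return `path` (write) or a `label_matrix` (read).
#' @export
write_label_matrix <- function(L, path) {
  df <- cbind(attr(L, "frame_map"), as.data.frame(unclass(L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lf_cols <- setdiff(names(df), c("patient_id", "frame_index"))
  L <- as.matrix(df[, lf_cols, drop = FALSE])
  storage.mode(L) <- "integer"
  attr(L, "frame_map") <- df[, c("patient_id", "frame_index")]
  attr(L, "lf_names") <- lf_cols
  class(L) <- c("label_matrix", class(L))
  L
}
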