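# Strict entity-level scoring: a predicted span counts only if its
# start, end and type all equal a gold span's (complete-span matching).

#' Extract entity spans from a BIO label sequence
#'
#' Maximal `B-X, I-X, ...` runs become spans.  Spans are reported with
#' 1-based inclusive `start`/`end` word indices (the natural R interval
#' convention; subtract 1 from `start` for 0-based half-open
#' coordinates).
#'
#' @param labels Character vector of grammar-valid IOB2 tags (run
#'   [repair_bio()] first if the sequence may be invalid).
#' @return data.frame with columns `start`, `end`, `type`, sorted by
#'   `start`; zero rows when no entity is present.
#' @export
#' @examples
#' extract_entities(c("B-Chem", "I-Chem", "O"))
extract_entities <- function(labels) {
  validate_bio(labels)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  open <- FALSE
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (startsWith(lab, "B-")) {
      starts <- c(starts, i); ends <- c(ends, i)
      types <- c(types, substring(lab, 3)); open <- TRUE
    } else if (startsWith(lab, "I-") && open) {
      ends[length(ends)] <- i
    } else {
      open <- FALSE
    }
  }
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

#' Strict entity-level precision, recall and F1
#'
#' Counts, per sentence, predicted spans that exactly match a gold span
#' in start, end and type (TP), predicted spans with no exact match
#' (FP), and gold spans with no exact match (FN), pooled over the corpus
#' and over entity types (micro-averaging).  Then
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2PR / (P + R)`, with a ratio defined as 0 when its denominator
#' is 0.
#'
#' @param gold List of gold label vectors (or data.frames from
#'   [extract_entities()]), one per sentence.
#' @param predicted List of predicted label vectors (or span
#'   data.frames), aligned with `gold`.
#' @return An `ner_eval` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, and `per_type` (data.frame with the same counts per entity
#'   type).
#' @export
#' @examples
#' score_entities(list(c("B-D", "I-D", "O")), list(c("B-D", "I-D", "O")))
score_entities <- function(gold, predicted) {
  if (length(gold) != length(predicted))
    stop(sprintf("gold has %d sentences but predictions have %d",
                 length(gold), length(predicted)))
  as_spans <- function(x) if (is.data.frame(x)) x else extract_entities(x)
  tp <- 0L; fp <- 0L; fn <- 0L
  type_counts <- list()
  bump <- function(type, what) {
    tc <- type_counts[[type]] %||% c(tp = 0L, fp = 0L, fn = 0L)
    tc[what] <- tc[what] + 1L
    type_counts[[type]] <<- tc
  }
  for (i in seq_along(gold)) {
    g <- as_spans(gold[[i]]); p <- as_spans(predicted[[i]])
    gk <- sprintf("%d:%d:%s", g$start, g$end, g$type)
    pk <- sprintf("%d:%d:%s", p$start, p$end, p$type)
    hit <- pk %in% gk
    tp <- tp + sum(hit); fp <- fp + sum(!hit)
    miss <- !(gk %in% pk)
    fn <- fn + sum(miss)
    for (j in which(hit)) bump(p$type[j], "tp")
    for (j in which(!hit)) bump(p$type[j], "fp")
    for (j in which(miss)) bump(g$type[j], "fn")
  }
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  overall <- prf(tp, fp, fn)
  per_type <- do.call(rbind, lapply(names(type_counts), function(ty) {
    tc <- type_counts[[ty]]
    data.frame(type = ty, tp = tc[["tp"]], fp = tc[["fp"]], fn = tc[["fn"]],
               t(prf(tc[["tp"]], tc[["fp"]], tc[["fn"]])),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = overall[["precision"]],
                 recall = overall[["recall"]], f1 = overall[["f1"]],
                 per_type = per_type %||%
                   data.frame(type = character(0), tp = integer(0),
                              fp = integer(0), fn = integer(0),
                              precision = numeric(0), recall = numeric(0),
                              f1 = numeric(0))),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat(sprintf("Entity-level (strict): TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score two BIO CoNLL files and write a JSON report
#'
#' @param gold_path Gold-standard two-column BIO file.
#' @param pred_path Prediction file in the same dialect (predictions are
#'   repaired with [repair_bio()] before scoring).
#' @param report_path Optional path for a JSON report with counts and
#'   per-type breakdown.
#' @return The `ner_eval` object, invisibly when `report_path` is set.
#' @export
evaluate_files <- function(gold_path, pred_path, report_path = NULL) {
  gold <- read_bio_conll(gold_path)
  pred <- read_bio_conll(pred_path)
  if (length(gold) != length(pred))
    stop("gold and prediction files have different sentence counts")
  sc <- score_entities(lapply(gold, `[[`, "labels"),
                       lapply(pred, function(s) repair_bio(s$labels)))
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(TP = sc$tp, FP = sc$fp, FN = sc$fn,
           precision = sc$precision, recall = sc$recall, f1 = sc$f1,
           per_type = sc$per_type),
      report_path, auto_unbox = TRUE, digits = NA)
    return(invisible(sc))
  }
  sc
}
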