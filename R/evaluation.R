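## Scoring: accuracy (specificity) = TP / (TP + FP),
## coverage (sensitivity) = TP / (TP + FN), per-protein macro
## aggregation, and the top-n comparison protocol.

canon_pairs <- function(p) {
  p <- matrix(as.integer(p), ncol = 2L)
  bad <- p[, 1L] > p[, 2L]
  if (any(bad)) p[bad, ] <- p[bad, 2:1]
  p
}

pair_keys <- function(p) paste(p[, 1L], p[, 2L])

#' Prediction accuracy (specificity)
#'
#' Percentage of predicted contacts that are observed:
#' 100 * TP / (TP + FP). Undefined (returned as `NA` with a warning)
#' when nothing was predicted; callers exclude such proteins from
#' macro averages rather than scoring them zero.
#'
#' @param predicted,observed integer pair matrices (columns i, j;
#'   order within a pair irrelevant).
#' @return percentage in \[0, 100\], or `NA`.
#' @export
accuracy <- function(predicted, observed) {
  predicted <- canon_pairs(predicted); observed <- canon_pairs(observed)
  if (nrow(predicted) == 0L) {
    warning("undefined accuracy: empty predicted set", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(pair_keys(predicted) %in% pair_keys(observed)) / nrow(predicted)
}

#' Prediction coverage (sensitivity)
#'
#' Percentage of observed contacts that are predicted:
#' 100 * TP / (TP + FN). Undefined when nothing was observed.
#'
#' @inheritParams accuracy
#' @return percentage in \[0, 100\], or `NA`.
#' @export
coverage <- function(predicted, observed) {
  predicted <- canon_pairs(predicted); observed <- canon_pairs(observed)
  if (nrow(observed) == 0L) {
    warning("undefined coverage: empty observed set", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(pair_keys(observed) %in% pair_keys(predicted)) / nrow(observed)
}

#' Per-protein contact counts and scores
#'
#' @inheritParams accuracy
#' @return list with `accuracy`, `coverage`, `n_correct`,
#'   `n_predicted`, `n_observed`.
#' @export
contact_scores <- function(predicted, observed) {
  predicted <- canon_pairs(predicted); observed <- canon_pairs(observed)
  tp <- sum(pair_keys(predicted) %in% pair_keys(observed))
  list(accuracy = if (nrow(predicted)) 100 * tp / nrow(predicted)
       else NA_real_,
       coverage = if (nrow(observed)) 100 * tp / nrow(observed)
       else NA_real_,
       n_correct = tp, n_predicted = nrow(predicted),
       n_observed = nrow(observed))
}

#' Aggregate per-protein scores
#'
#' Unweighted (macro) mean over proteins, with sample standard
#' deviation and standard error of the mean. Proteins with undefined
#' scores (empty prediction or truth sets) are excluded from the
#' average and counted in `n_excluded`.
#'
#' @param per_protein a data frame with columns `accuracy` and
#'   `coverage` (one row per protein), or a list of
#'   [contact_scores()] results.
#' @return an object of class `score_report`: list with `per_protein`
#'   and `summary` (metric, mean, sd, se, n, n_excluded).
#' @export
aggregate_scores <- function(per_protein) {
  if (!is.data.frame(per_protein)) {
    per_protein <- do.call(rbind, lapply(per_protein, function(s)
      as.data.frame(s[c("accuracy", "coverage", "n_correct",
                        "n_predicted", "n_observed")])))
  }
  if (nrow(per_protein) == 0L) stop2("nothing to aggregate")
  one <- function(v) {
    ok <- v[!is.na(v)]
    if (length(ok) == 0L) stop2("nothing to aggregate")
    data.frame(mean = mean(ok),
               sd = if (length(ok) > 1L) stats::sd(ok) else 0,
               se = if (length(ok) > 1L)
                 stats::sd(ok) / sqrt(length(ok)) else 0,
               n = length(ok), n_excluded = sum(is.na(v)))
  }
  summ <- rbind(cbind(metric = "accuracy", one(per_protein$accuracy)),
                cbind(metric = "coverage", one(per_protein$coverage)))
  structure(list(per_protein = per_protein, summary = summ),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("%s: %.2f%% (sd %.2f, se %.2f, n = %d%s)\n",
                s$metric[r], s$mean[r], s$sd[r], s$se[r], s$n[r],
                if (s$n_excluded[r] > 0)
                  paste0(", ", s$n_excluded[r], " excluded") else ""))
  invisible(x)
}

#' Select the n highest-probability predicted pairs
#'
#' Ties are broken deterministically by smaller i, then smaller j;
#' `n` beyond the number of available pairs returns all pairs.
#'
#' @param map a [predict_map()] result, or any list with elements
#'   `pairs` and `prob`.
#' @param n number of pairs to keep (>= 1).
#' @return integer pair matrix (columns i, j), at most n rows.
#' @export
top_n_select <- function(map, n) {
  stopifnot(n >= 1)
  o <- order(-map$prob, map$pairs[, 1L], map$pairs[, 2L])
  o <- o[seq_len(min(n, length(o)))]
  map$pairs[o, , drop = FALSE]
}

#' Top-n comparison protocol
#'
#' Evaluates a predictor at three list sizes derived from the number
#' of true contacts T: n = floor(T/2), floor(2T/3) and T; the final
#' indices are the means over the three settings. By default T is the
#' total true-contact count of the whole test set and the top-n list
#' is pooled across proteins; `per_protein = TRUE` instead applies
#' the protocol within each protein and macro-averages.
#'
#' @param maps list of [predict_map()] results (or `pairs`/`prob`
#'   lists), one per protein.
#' @param truths list of observed contact-pair matrices, aligned with
#'   `maps` (already restricted to the evaluated separation mask).
#' @param per_protein logical, see above.
#' @return an object of class `compare_report`: list with `settings`
#'   (data frame: n, accuracy, coverage) and the mean `accuracy` and
#'   `coverage`.
#' @export
compare_protocol <- function(maps, truths, per_protein = FALSE) {
  stopifnot(length(maps) == length(truths))
  total_T <- sum(vapply(truths, function(t) nrow(canon_pairs(t)),
                        integer(1L)))
  if (total_T == 0L) stop2("no observed contacts")

  if (!per_protein) {
    prot <- rep(seq_along(maps),
                vapply(maps, function(m) length(m$prob), integer(1L)))
    pairs <- do.call(rbind, lapply(maps, function(m) canon_pairs(m$pairs)))
    prob <- unlist(lapply(maps, function(m) m$prob))
    truth_keys <- lapply(truths, function(t) pair_keys(canon_pairs(t)))
    o <- order(-prob, prot, pairs[, 1L], pairs[, 2L])
    ns <- c(floor(total_T / 2), floor(2 * total_T / 3), total_T)
    rows <- lapply(ns, function(n) {
      sel <- o[seq_len(min(n, length(o)))]
      tp <- sum(mapply(function(p, k) k %in% truth_keys[[p]],
                       prot[sel], pair_keys(pairs[sel, , drop = FALSE])))
      data.frame(n = n, accuracy = 100 * tp / length(sel),
                 coverage = 100 * tp / total_T)
    })
  } else {
    ## macro: protocol within each protein, averaged over proteins
    per <- lapply(seq_along(maps), function(p) {
      Tt <- nrow(canon_pairs(truths[[p]]))
      if (Tt == 0L) return(NULL)
      ns <- c(floor(Tt / 2), floor(2 * Tt / 3), Tt)
      ns[ns < 1L] <- 1L
      t(vapply(ns, function(n) {
        sel <- top_n_select(maps[[p]], n)
        s <- contact_scores(sel, truths[[p]])
        c(s$accuracy, s$coverage)
      }, numeric(2L)))
    })
    per <- per[!vapply(per, is.null, logical(1L))]
    acc <- Reduce(`+`, lapply(per, function(m) m[, 1L])) / length(per)
    cov <- Reduce(`+`, lapply(per, function(m) m[, 2L])) / length(per)
    rows <- lapply(1:3, function(r)
      data.frame(n = NA_integer_, accuracy = acc[r], coverage = cov[r]))
  }
  settings <- do.call(rbind, rows)
  structure(list(settings = settings,
                 accuracy = mean(settings$accuracy),
                 coverage = mean(settings$coverage)),
            class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  print(x$settings)
  cat(sprintf("mean over settings: accuracy %.2f%%, coverage %.2f%%\n",
              x$accuracy, x$coverage))
  invisible(x)
}

#' Write a score report to TSV and JSON
#'
#' @param report a [aggregate_scores()] `score_report`.
#' @param prefix output prefix; writes `<prefix>.tsv` (per-protein
#'   rows) and `<prefix>.json` (summary).
#' @return the prefix, invisibly.
#' @export
write_score_report <- function(report, prefix) {
  utils::write.table(report$per_protein, paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$summary, paste0(prefix, ".json"),
                       digits = NA, dataframe = "rows")
  invisible(prefix)
}
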