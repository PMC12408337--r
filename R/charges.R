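## Partial charges from refined ionic fractions: dq = nu * dZ, with
## uncertainties propagated from the refinement covariance; merging across
## datasets, group sums, and comparison with reference charge sets.

#' Extract per-atom partial charges from a refinement result
#'
#' \eqn{\delta q_j = \nu_j \Delta Z_j} with
#' \eqn{\sigma(\delta q_j) = |\Delta Z_j| \sigma(\nu_j)}. Fixed-neutral atoms
#' are reported as 0 with esu 0 and a `fixed` flag. The nu covariance block
#' (scaled to charge units) is attached as attribute `"cov"` for group sums.
#'
#' @param result A [refine()] result.
#' @param model The model the result refers to (defaults to `result$model`).
#' @param force Extract even from an unconverged result.
#' @return Data frame of class `charge_set` with columns `label`, `element`,
#'   `dZ`, `nu`, `dq`, `esu`, `fixed`.
#' @export
extract_charges <- function(result, model = result$model, force = FALSE) {
  if (!result$converged && !force)
    stop("refinement did not converge; use force = TRUE to extract anyway",
         call. = FALSE)
  labels <- site_labels(model)
  nu_rows <- which(result$map$kind == "nu")
  nu_sites <- result$map$site[nu_rows]
  out <- data.frame(label = labels,
                    element = vapply(model$sites, function(s) s$ion$element, ""),
                    dZ = vapply(model$sites, function(s) s$ion$dZ, 0L),
                    nu = vapply(model$sites, function(s) s$nu, 0),
                    dq = NA_real_, esu = NA_real_,
                    fixed = vapply(model$sites, function(s) isTRUE(s$nu_fixed), TRUE),
                    stringsAsFactors = FALSE)
  out$dq <- out$nu * out$dZ
  out$esu <- 0
  for (i in seq_along(nu_rows)) {
    j <- nu_sites[i]
    out$esu[j] <- abs(out$dZ[j]) * result$esd[nu_rows[i]]
  }
  out$dq[out$fixed] <- out$nu[out$fixed] * out$dZ[out$fixed]
  ## charge-unit covariance of the free fractions
  dzv <- out$dZ[nu_sites]
  covq <- result$cov[nu_rows, nu_rows, drop = FALSE] * tcrossprod(dzv)
  dimnames(covq) <- list(labels[nu_sites], labels[nu_sites])
  attr(out, "cov") <- covq
  class(out) <- c("charge_set", class(out))
  out
}

#' Format charges in crystallographic bracket notation
#'
#' `-0.50(3)` means -0.50 e with a standard uncertainty of 0.03 e.
#'
#' @param dq Charges (e).
#' @param esu Standard uncertainties (e).
#' @param digits Decimal places for the value.
#' @return Character vector.
#' @export
format_charge <- function(dq, esu, digits = 2L) {
  mapply(function(q, s) {
    if (s <= 0) return(sprintf(paste0("%.", digits, "f"), q))
    sprintf(paste0("%.", digits, "f(%d)"), q, as.integer(round(s * 10^digits)))
  }, dq, esu)
}

#' Inverse-variance weighted merge of charge sets
#'
#' Per label, \eqn{\bar q = \sum(q_i/\sigma_i^2) / \sum(1/\sigma_i^2)} and
#' \eqn{\bar\sigma = (\sum 1/\sigma_i^2)^{-1/2}}. Labels missing from some
#' sets are combined over the sets that carry them; the `n_sets` column
#' records the coverage. Zero-esu values are accepted only when every
#' contributing value agrees exactly.
#'
#' @param sets List of `charge_set` data frames.
#' @return Merged `charge_set`-like data frame with columns `label`, `dq`,
#'   `esu`, `n_sets`.
#' @export
combine_charge_sets <- function(sets) {
  if (length(sets) < 1L) stop("need at least one charge set", call. = FALSE)
  if (length(sets) == 1L) {
    out <- sets[[1]][, c("label", "dq", "esu")]
    out$n_sets <- 1L
    return(out)
  }
  labels <- unique(unlist(lapply(sets, function(s) s$label)))
  rows <- lapply(labels, function(lab) {
    q <- numeric(); sg <- numeric()
    for (s in sets) {
      i <- match(lab, s$label)
      if (!is.na(i)) { q <- c(q, s$dq[i]); sg <- c(sg, s$esu[i]) }
    }
    if (any(sg == 0)) {
      ## a zero-esu value is exact: admissible only if all values agree
      if (max(q) - min(q) > 1e-12)
        stop("zero-esu value disagrees with other sets for label ", lab,
             call. = FALSE)
      return(data.frame(label = lab, dq = q[1], esu = 0, n_sets = length(q)))
    }
    w <- 1 / sg^2
    data.frame(label = lab, dq = sum(w * q) / sum(w), esu = 1 / sqrt(sum(w)),
               n_sets = length(q))
  })
  do.call(rbind, rows)
}

#' Summed charge of a group of atoms with propagated uncertainty
#'
#' Uses the full covariance block of the contributing fractions when
#' available; falls back to the independent-sum uncertainty (flagged in the
#' `independent` attribute) otherwise.
#'
#' @param set A `charge_set` from [extract_charges()].
#' @param labels Atom labels to sum (empty gives 0 +- 0).
#' @param covariance Optional covariance matrix in charge units overriding
#'   the one attached to `set`.
#' @return List with `total`, `esu`, `independent`.
#' @export
group_charge <- function(set, labels, covariance = attr(set, "cov")) {
  if (length(labels) == 0L) return(list(total = 0, esu = 0, independent = FALSE))
  i <- match(labels, set$label)
  if (anyNA(i)) stop("unknown label(s): ",
                     paste(labels[is.na(i)], collapse = ", "), call. = FALSE)
  total <- sum(set$dq[i])
  have_cov <- !is.null(covariance) &&
    all(labels[!set$fixed[i]] %in% rownames(covariance))
  if (have_cov) {
    free_labels <- labels[!set$fixed[i]]
    cc <- covariance[free_labels, free_labels, drop = FALSE]
    esu <- sqrt(max(sum(cc), 0))
    independent <- FALSE
  } else {
    esu <- sqrt(sum(set$esu[i]^2))
    independent <- TRUE
  }
  list(total = total, esu = esu, independent = independent)
}

#' Pearson correlation between two charge sets
#'
#' Pairs atoms by exact label (optionally through an alias map
#' `c(theirs = ours)`), optionally drops hydrogens, and computes the
#' standard Pearson coefficient.
#'
#' @param set_a Experimental `charge_set` (needs `label` and `dq`).
#' @param set_b Reference set: data frame with `label` and a charge column
#'   (`dq` or `q`).
#' @param include_hydrogens Keep hydrogen atoms (identified by an `element`
#'   column when present, else by labels starting with H).
#' @param aliases Named character vector mapping `set_b` labels to `set_a`
#'   labels.
#' @return Object of class `charge_comparison`: `pearson`, `n`, `pairs`
#'   (data frame), `unmatched_a`, `unmatched_b`.
#' @export
charge_pearson <- function(set_a, set_b, include_hydrogens = TRUE,
                           aliases = NULL) {
  qb_col <- if ("dq" %in% names(set_b)) "dq" else "q"
  lab_b <- as.character(set_b$label)
  if (!is.null(aliases)) {
    hit <- lab_b %in% names(aliases)
    lab_b[hit] <- aliases[lab_b[hit]]
  }
  i <- match(set_a$label, lab_b)
  matched <- !is.na(i)
  pairs <- data.frame(label = set_a$label[matched],
                      q_exp = set_a$dq[matched],
                      q_ref = set_b[[qb_col]][i[matched]])
  is_h <- if ("element" %in% names(set_a)) set_a$element[matched] == "H"
          else grepl("^H", pairs$label)
  if (!include_hydrogens) pairs <- pairs[!is_h, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  if (stats::sd(pairs$q_exp) == 0 || stats::sd(pairs$q_ref) == 0)
    stop("zero variance: Pearson coefficient undefined", call. = FALSE)
  structure(list(pearson = stats::cor(pairs$q_exp, pairs$q_ref),
                 n = nrow(pairs), pairs = pairs,
                 unmatched_a = set_a$label[!matched],
                 unmatched_b = setdiff(lab_b, set_a$label)),
            class = "charge_comparison")
}

#' @export
print.charge_comparison <- function(x, ...) {
  cat(sprintf("<charge_comparison> Pearson r = %.4f over %d pairs\n",
              x$pearson, x$n))
  if (length(x$unmatched_a))
    cat("  unmatched (experimental):", paste(x$unmatched_a, collapse = ", "), "\n")
  if (length(x$unmatched_b))
    cat("  unmatched (reference):", paste(x$unmatched_b, collapse = ", "), "\n")
  invisible(x)
}

#' Augment a hydrogen-free charge set with average hydrogen charges
#'
#' Appends `n_h` hydrogen entries each carrying minus the summed non-H charge
#' divided by `n_h`, i.e. the average hydrogen charge a neutral total
#' implies. This reproduces the control analysis in which hydrogen charges
#' are not measured but counterbalanced.
#'
#' @param set A `charge_set`-like data frame without hydrogens.
#' @param n_h Positive number of hydrogen entries to append.
#' @return Data frame with the appended `Havg1..n` rows.
#' @export
average_h_augmentation <- function(set, n_h) {
  n_h <- as.integer(n_h)
  if (is.na(n_h) || n_h <= 0L) stop("n_h must be a positive integer", call. = FALSE)
  qh <- -sum(set$dq) / n_h
  add <- data.frame(label = sprintf("Havg%d", seq_len(n_h)), dq = qh)
  for (col in setdiff(names(set), names(add))) {
    add[[col]] <- if (col == "element") "H" else if (col == "esu") 0
                  else if (is.numeric(set[[col]])) NA_real_ else NA
  }
  rbind(set[, names(set)], add[, names(set)])
}

#' Write a delimiter-separated charge report
#' @param set A `charge_set`.
#' @param path Output file.
#' @return Invisibly, the written data frame.
#' @export
write_charge_table <- function(set, path) {
  df <- as.data.frame(set)
  if (all(c("dq", "esu") %in% names(df)))
    df$formatted <- format_charge(df$dq, df$esu)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a labelled reference charge table
#'
#' Two-column (label, charge) whitespace- or tab-separated text, with or
#' without a header line.
#'
#' @param path Input file.
#' @return Data frame with columns `label` and `q`.
#' @export
read_reference_charges <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*\\S+\\s+[-+0-9.eE]+\\s*$", first) ||
    grepl("label", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("label", "q")
  df$q <- as.numeric(df$q)
  df[, c("label", "q")]
}
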