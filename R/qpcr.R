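# ChIP-qPCR enrichment math: percent input, internally normalized log2
# fold enrichment, replicate statistics, and delta-Ct relative abundance.

#' Percent input from paired Ct values
#'
#' `100 * eff^((ct_input - log_eff(1/input_fraction)) - ct_ip)`: the input
#' Ct is first adjusted for the input dilution (with 1% input and perfect
#' doubling the adjustment is log2(100) cycles), then compared with the IP
#' Ct assuming `efficiency`-fold amplification per cycle.
#'
#' @param ct_ip,ct_input Ct values (cycles).
#' @param input_fraction fraction of chromatin kept as input (default 1%).
#' @param efficiency per-cycle amplification factor (default 2).
#' @return percent-input values.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01,
                          efficiency = 2) {
  if (efficiency <= 0) stop("efficiency must be positive")
  adj <- log(1 / input_fraction, base = efficiency)
  100 * efficiency^((ct_input - adj) - ct_ip)
}

#' Internally normalized ChIP-qPCR enrichment
#'
#' Per replicate, each locus' percent input is divided by the percent input
#' of the internal-control locus (a locus not bound by the factor) and
#' log2-transformed. Replicate values are averaged per condition with the
#' standard error of the mean; when two conditions are present a two-sided
#' two-sample (equal-variance) t-test compares their replicate log2 fold
#' enrichments per locus.
#'
#' @param records long-format data.frame with columns `locus`, `role`
#'   (`target` / `internal_control`), `template` (`IP` / `input`),
#'   `condition`, `replicate`, `ct`, `input_fraction`.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return list with `per_replicate` (locus, condition, replicate, log2fe),
#'   `summary` (locus, condition, mean_log2fe, sem, n) and `tests` (locus,
#'   p two-sided between the two conditions; `NULL` with one condition).
#' @export
qpcr_enrichment <- function(records, efficiency = 2) {
  need <- c("locus", "role", "template", "condition", "replicate", "ct",
            "input_fraction")
  stopifnot(all(need %in% names(records)))
  ctrl_loci <- unique(records$locus[records$role == "internal_control"])
  if (length(ctrl_loci) != 1) {
    stop("exactly one internal-control locus is required")
  }
  key <- interaction(records$locus, records$condition, records$replicate,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    ip <- r$ct[r$template == "IP"]
    inp <- r$ct[r$template == "input"]
    if (length(ip) != 1 || length(inp) != 1) {
      stop(sprintf("missing or duplicated IP/input Ct for %s / %s / rep %s",
                   r$locus[1], r$condition[1], r$replicate[1]))
    }
    data.frame(locus = r$locus[1], condition = r$condition[1],
               replicate = r$replicate[1],
               pin = percent_input(ip, inp, r$input_fraction[1],
                                   efficiency),
               stringsAsFactors = FALSE)
  })
  pin <- do.call(rbind, rows)
  ctrl <- pin[pin$locus == ctrl_loci, ]
  m <- merge(pin, ctrl[, c("condition", "replicate", "pin")],
             by = c("condition", "replicate"),
             suffixes = c("", "_ctrl"), all.x = TRUE)
  if (anyNA(m$pin_ctrl)) {
    bad <- m[is.na(m$pin_ctrl), ][1, ]
    stop(sprintf("no internal-control measurement pairs %s / rep %s",
                 bad$condition, bad$replicate))
  }
  m$log2fe <- log2(m$pin / m$pin_ctrl)
  per_rep <- m[order(m$locus, m$condition, m$replicate),
               c("locus", "condition", "replicate", "log2fe")]
  rownames(per_rep) <- NULL

  agg <- do.call(rbind, lapply(split(per_rep,
                                     interaction(per_rep$locus,
                                                 per_rep$condition,
                                                 drop = TRUE)),
                               function(r) {
    data.frame(locus = r$locus[1], condition = r$condition[1],
               mean_log2fe = mean(r$log2fe),
               sem = if (nrow(r) > 1) stats::sd(r$log2fe) / sqrt(nrow(r))
                     else NA_real_,
               n = nrow(r), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  tests <- NULL
  conds <- unique(per_rep$condition)
  if (length(conds) == 2) {
    tests <- do.call(rbind, lapply(split(per_rep, per_rep$locus),
                                   function(r) {
      a <- r$log2fe[r$condition == conds[1]]
      b <- r$log2fe[r$condition == conds[2]]
      p <- if (length(a) >= 2 && length(b) >= 2 &&
               (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        stats::t.test(a, b, var.equal = TRUE)$p.value
      } else NA_real_
      data.frame(locus = r$locus[1], p = p, stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(per_replicate = per_rep, summary = agg, tests = tests,
       internal_control = ctrl_loci)
}

#' Delta-Ct relative transcript abundance
#'
#' Technical-replicate Ct values are averaged first; the relative abundance
#' is then `2^(mean(ct_reference) - mean(ct_target))`, i.e. one cycle of
#' difference corresponds to a two-fold abundance change.
#'
#' @param ct_target,ct_reference technical-replicate Ct vectors of equal
#'   length.
#' @return scalar relative abundance.
#' @export
relative_abundance <- function(ct_target, ct_reference) {
  if (!length(ct_target) || length(ct_target) != length(ct_reference)) {
    stop("paired target/reference Ct values are required")
  }
  if (anyNA(ct_target) || anyNA(ct_reference)) {
    stop("missing Ct value in a replicate pair")
  }
  2^(mean(ct_reference) - mean(ct_target))
}
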