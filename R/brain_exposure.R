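# Brain-exposure scoring: combine physicochemical sub-scores with
# efflux-substrate predictions into a single integer score in [-1, 3], and
# stratify compounds by measured unbound brain-to-plasma ratio (Kp,uu).

#' Physicochemical sub-scores for brain exposure
#'
#' Each property scores 1 when its brain-penetration-favorable inequality
#' holds, with inclusive bounds: TPSA <= 90 A^2, HBD <= 5, HBA <= 10;
#' compounds exceeding a threshold score 0 for that property.
#'
#' @param tpsa topological polar surface area (A^2), or a data.frame with
#'   columns `tpsa`, `hbd`, `hba` (as from [compute_brain_props()]).
#' @param hbd,hba hydrogen-bond donor / acceptor counts (ignored when
#'   `tpsa` is a data.frame).
#' @return data.frame with integer columns `s_tpsa`, `s_hbd`, `s_hba`.
#' @export
#' @examples
#' sub_scores(90, 5, 10)   # all three score 1 (inclusive bounds)
#' sub_scores(90.1, 6, 11) # all three score 0
sub_scores <- function(tpsa, hbd, hba) {
  if (is.data.frame(tpsa)) {
    hbd <- tpsa$hbd; hba <- tpsa$hba; tpsa <- tpsa$tpsa
  }
  stopifnot(all(tpsa >= 0), all(hbd >= 0), all(hba >= 0))
  data.frame(s_tpsa = as.integer(tpsa <= 90),
             s_hbd = as.integer(hbd <= 5),
             s_hba = as.integer(hba <= 10))
}

#' Efflux-substrate flag from P-gp and BCRP probabilities
#'
#' A predicted probability of 0.5 or higher classifies a compound as a
#' substrate. In the default `"either"` mode the flag is 1 when the
#' compound is predicted a substrate of P-gp and/or BCRP; the single
#' transporter modes use only the respective probability.
#'
#' @param pgp_prob,bcrp_prob predicted substrate probabilities in \[0, 1\].
#' @param mode `"either"`, `"pgp"` or `"bcrp"`.
#' @return integer vector of 0/1 flags.
#' @export
#' @examples
#' efflux_flag(0.5, 0.1)                 # 1
#' efflux_flag(0.2, 0.9, mode = "pgp")   # 0
efflux_flag <- function(pgp_prob, bcrp_prob, mode = c("either", "pgp", "bcrp")) {
  mode <- match.arg(mode)
  stopifnot(all(pgp_prob >= 0 & pgp_prob <= 1),
            all(bcrp_prob >= 0 & bcrp_prob <= 1))
  p <- switch(mode,
              either = pmax(pgp_prob, bcrp_prob),
              pgp = pgp_prob,
              bcrp = bcrp_prob)
  as.integer(p >= 0.5)
}

#' Brain-exposure score
#'
#' Sum of the three physicochemical sub-scores minus the efflux-substrate
#' flag, giving an integer in \{-1, 0, 1, 2, 3\}: 3 for a compound meeting
#' all physicochemical criteria and predicted a nonsubstrate, -1 for the
#' mirrored case.
#'
#' @param subs data.frame from [sub_scores()].
#' @param s_efflux integer 0/1 flags from [efflux_flag()].
#' @return integer vector of scores.
#' @export
#' @examples
#' exposure_score(sub_scores(50, 2, 4), 0)  # 3
exposure_score <- function(subs, s_efflux) {
  stopifnot(all(s_efflux %in% c(0, 1)))
  score <- subs$s_tpsa + subs$s_hbd + subs$s_hba - s_efflux
  stopifnot(all(score >= -1 & score <= 3))
  as.integer(score)
}

#' Assemble the full exposure-record table
#'
#' Combines physicochemical properties, the two transporter substrate
#' probabilities, the derived sub-scores and score, and (optionally) the
#' measured Kp,uu value into one table. Compounds lacking a usable
#' probability are emitted with a missing score and counted in a warning.
#'
#' @param props data.frame from [compute_brain_props()] (must carry
#'   `chemical_id`).
#' @param pgp_prob,bcrp_prob substrate probabilities aligned with `props`.
#' @param kpuu optional data.frame (`chemical_id`, `kpuu`) of measured
#'   unbound brain-to-plasma ratios.
#' @param mode efflux flag mode, see [efflux_flag()].
#' @return data.frame with one row per compound: sub-scores, `s_efflux`,
#'   `score`, probabilities, and `kpuu` (NA where unmeasured).
#' @export
exposure_table <- function(props, pgp_prob, bcrp_prob, kpuu = NULL,
                           mode = "either") {
  stopifnot(nrow(props) == length(pgp_prob),
            nrow(props) == length(bcrp_prob))
  usable <- !is.na(pgp_prob) & !is.na(bcrp_prob)
  subs <- sub_scores(props)
  out <- data.frame(chemical_id = props$chemical_id, subs,
                    s_efflux = NA_integer_, score = NA_integer_,
                    pgp_prob = pgp_prob, bcrp_prob = bcrp_prob,
                    kpuu = NA_real_, stringsAsFactors = FALSE)
  if (any(usable)) {
    out$s_efflux[usable] <- efflux_flag(pgp_prob[usable], bcrp_prob[usable],
                                        mode = mode)
    out$score[usable] <- exposure_score(subs[usable, , drop = FALSE],
                                        out$s_efflux[usable])
  }
  if (any(!usable)) {
    warning(sum(!usable), " compound(s) without usable efflux predictions; ",
            "score left missing")
  }
  if (!is.null(kpuu)) {
    out$kpuu <- kpuu$kpuu[match(out$chemical_id, kpuu$chemical_id)]
  }
  out
}

#' Stratify exposure records by measured Kp,uu and summarize enrichment
#'
#' Splits compounds at the given Kp,uu cut (0.1 separates low from high
#' brain exposure; 1.0 isolates very-high-exposure compounds), tabulates
#' predicted substrates and nonsubstrates and the score distribution per
#' stratum, and reports the substrate-likelihood ratio: the fraction of
#' predicted substrates in the low stratum divided by that in the high
#' stratum. An infinite ratio (no predicted substrates among high-exposure
#' compounds) is reported as `Inf` with `censored = TRUE`.
#'
#' @param records data.frame from [exposure_table()] with `kpuu` present.
#' @param cut Kp,uu threshold (default 0.1).
#' @return list with `cut`, `counts` (stratum x substrate/nonsubstrate),
#'   `score_distribution` (stratum x score -1..3), `likelihood_ratio`,
#'   `censored`.
#' @export
stratify_and_summarize <- function(records, cut = 0.1) {
  rec <- records[!is.na(records$kpuu) & !is.na(records$s_efflux), , drop = FALSE]
  if (nrow(rec) == 0) stop("no records with both kpuu and an efflux prediction")
  stratum <- factor(ifelse(rec$kpuu >= cut, "high", "low"),
                    levels = c("low", "high"))
  counts <- table(stratum,
                  ifelse(rec$s_efflux == 1, "substrate", "nonsubstrate"))
  score_distribution <- table(stratum,
                              factor(rec$score, levels = -1:3))
  frac_sub <- function(s) {
    idx <- stratum == s
    if (!any(idx)) return(NA_real_)
    mean(rec$s_efflux[idx] == 1)
  }
  lo <- frac_sub("low"); hi <- frac_sub("high")
  ratio <- if (is.na(lo) || is.na(hi)) NA_real_
           else if (hi == 0 && lo == 0) 1
           else if (hi == 0) Inf
           else lo / hi
  list(cut = cut, counts = counts, score_distribution = score_distribution,
       likelihood_ratio = ratio,
       censored = is.infinite(ratio))
}
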