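#' Respiration rate from 15-second flank counts
#'
#' Flank movements are counted for 15 s and multiplied by 4 to give breaths
#' per minute.
#'
#' @param flank_count_15s non-negative count(s).
#' @return breaths per minute.
#' @export
rr_from_counts <- function(flank_count_15s) {
  if (any(flank_count_15s < 0)) stop("rr_from_counts: negative count")
  4 * flank_count_15s
}

#' Single-pass outlier filter
#'
#' Removes records deviating by more than \code{k} standard deviations from
#' the trait mean, with mean and SD computed once on the unfiltered records
#' of each trait (no iterative re-estimation). Respiration-rate records are
#' additionally restricted to the physiological band [12, 172] bpm.
#'
#' @param pheno long-format phenotype table with \code{trait} and \code{value}.
#' @param k SD multiplier (default 3.5).
#' @param rr_trait trait name(s) carrying respiration rate, subject to the
#'   bpm band; set NULL to disable.
#' @param rr_bounds numeric length 2, retained closed interval for RR.
#' @return list of class \code{filter_result}: \code{data} (retained records),
#'   \code{report} (data frame: row index in the input, trait, reason in
#'   \{sd_outlier, rr_bounds\}).
#' @export
filter_outliers <- function(pheno, k = 3.5, rr_trait = "RR",
                            rr_bounds = c(12, 172)) {
  stopifnot(all(c("trait", "value") %in% names(pheno)), k >= 0)
  drop <- rep(FALSE, nrow(pheno))
  reason <- rep(NA_character_, nrow(pheno))
  for (tr in unique(pheno$trait)) {
    sel <- which(pheno$trait == tr)
    v <- pheno$value[sel]
    if (length(sel) >= 2) {
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (is.finite(s) && s > 0) {
        out <- abs(v - m) > k * s
        out[is.na(out)] <- FALSE
        drop[sel[out]] <- TRUE
        reason[sel[out]] <- "sd_outlier"
      }
    }
    if (!is.null(rr_trait) && tr %in% rr_trait) {
      out <- v < rr_bounds[1] | v > rr_bounds[2]
      out[is.na(out)] <- FALSE
      new <- sel[out & !drop[sel]]
      drop[new] <- TRUE
      reason[new] <- "rr_bounds"
    }
  }
  report <- data.frame(record = which(drop),
                       trait = pheno$trait[drop],
                       reason = reason[drop], stringsAsFactors = FALSE)
  res <- pheno[!drop, , drop = FALSE]
  structure(list(data = res, report = report), class = "filter_result")
}

#' Derive the vaginal-temperature trait family from raw 10-min records
#'
#' From the continuous 10-min series (trait \code{T_Vall}), hourly values are
#' the mean of the up-to-6 records within each target clock hour. The derived
#' traits are:
#' \itemize{
#'   \item \code{T_Vall}: every raw 10-min record;
#'   \item \code{T_V4days}: the hourly values at 8:00, 12:00, 16:00 and 20:00
#'     over all collection days (up to 16 records/animal over 4 days);
#'   \item \code{T_V8h}, \code{T_V12h}, \code{T_V16h}, \code{T_V20h}: the
#'     daily hourly value at that fixed hour (up to 1 record/animal/day);
#'   \item \code{T_V8hS}, \code{T_V12hS}, \code{T_V16hS}, \code{T_V20hS}: the
#'     hour value on the first collection day only (single record).
#' }
#' Animals without any record in a target hour simply have no derived record
#' for that hour.
#'
#' @param tv raw table with columns \code{animal_id}, \code{day} (integer
#'   collection day, 1 = first), \code{time} (decimal clock hours of the
#'   10-min tick), \code{value}, plus any systematic-effect columns, which are
#'   carried through (first value per animal-day-hour).
#' @param hours target clock hours (default \code{c(8, 12, 16, 20)}).
#' @return phenotype table with the derived \code{trait} column.
#' @export
derive_tv_traits <- function(tv, hours = c(8, 12, 16, 20)) {
  stopifnot(all(c("animal_id", "day", "time", "value") %in% names(tv)))
  keep_cols <- setdiff(names(tv), c("trait", "value", "time"))
  tv$trait <- "T_Vall"
  all_rec <- tv[, c("trait", setdiff(names(tv), "trait"))]

  hr <- floor(tv$time)
  in_target <- hr %in% hours
  sub <- tv[in_target, , drop = FALSE]
  sub$hour <- floor(sub$time)
  key <- interaction(sub$animal_id, sub$day, sub$hour, drop = TRUE)
  first <- !duplicated(key)
  hourly <- sub[first, c("animal_id", "day", "hour",
                         setdiff(keep_cols, c("animal_id", "day"))),
                drop = FALSE]
  hourly$value <- as.numeric(tapply(sub$value, key, mean))[
    match(key[first], levels(key))]
  hourly$time <- hourly$hour

  blocks <- list()
  h4 <- hourly; h4$trait <- "T_V4days"
  blocks[["T_V4days"]] <- h4
  for (h in hours) {
    bh <- hourly[hourly$hour == h, , drop = FALSE]
    bh$trait <- sprintf("T_V%dh", h)
    blocks[[sprintf("T_V%dh", h)]] <- bh
    bs <- bh[bh$day == min(tv$day), , drop = FALSE]
    bs$trait <- sprintf("T_V%dhS", h)
    blocks[[sprintf("T_V%dhS", h)]] <- bs
  }
  derived <- do.call(rbind, lapply(blocks, function(b) {
    b$hour <- NULL
    b[, c("trait", "animal_id", "day", "time", "value",
          setdiff(names(b), c("trait", "animal_id", "day", "time", "value")))]
  }))
  all_rec <- all_rec[, names(derived), drop = FALSE]
  out <- rbind(all_rec, derived)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Respiration efficiency: per-animal slope of T_V on RR
#'
#' Ordinary-least-squares slope of vaginal temperature (response) on
#' respiration rate (covariate) over an animal's available paired records at
#' the 8:00 and 16:00 measurements across the collection days (degC per bpm).
#' A smaller slope means more cooling per breath; no sign flip is applied.
#' Animals with fewer than 2 complete pairs or with zero RR variance get a
#' missing value.
#'
#' @param rr data frame of RR records: \code{animal_id}, \code{day},
#'   \code{time}, \code{value}.
#' @param tv_hourly data frame of matching hourly T_V values with the same
#'   key columns.
#' @param hours clock hours used for pairing (default \code{c(8, 16)}).
#' @return data frame: \code{animal_id}, \code{value} (slope, NA when not
#'   estimable), \code{n_pairs}.
#' @export
respiration_efficiency <- function(rr, tv_hourly, hours = c(8, 16)) {
  stopifnot(all(c("animal_id", "day", "time", "value") %in% names(rr)),
            all(c("animal_id", "day", "time", "value") %in% names(tv_hourly)))
  rr <- rr[rr$time %in% hours, c("animal_id", "day", "time", "value")]
  tv <- tv_hourly[tv_hourly$time %in% hours,
                  c("animal_id", "day", "time", "value")]
  names(rr)[4] <- "rr"; names(tv)[4] <- "tv"
  pairs <- merge(rr, tv, by = c("animal_id", "day", "time"))
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  ids <- sort(unique(c(rr$animal_id, tv$animal_id)))
  slope <- rep(NA_real_, length(ids))
  np <- integer(length(ids))
  for (i in seq_along(ids)) {
    pp <- pairs[pairs$animal_id == ids[i], , drop = FALSE]
    np[i] <- nrow(pp)
    if (nrow(pp) >= 2 && sd(pp$rr) > 0)
      slope[i] <- cov(pp$rr, pp$tv) / var(pp$rr)
  }
  data.frame(animal_id = ids, value = slope, n_pairs = np,
             stringsAsFactors = FALSE)
}
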