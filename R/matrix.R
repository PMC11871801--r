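# Age- and region-grouped contact matrices: raw per-participant-per-day
# rates, reciprocity correction against population sizes, and
# participant-level bootstrap confidence intervals.

# Per-participant contact tallies within a record selection.
# Returns Xp (participants x contact groups), the participant group factor,
# the per-participant day denominator, and the unknown-group exclusion count.
prep_matrix_data <- function(diary, part_group, contact_group, keep, n_days) {
  groups <- levels(part_group)
  cg <- contact_group[keep]
  sel <- !is.na(cg)
  n_excluded <- sum(!sel)
  ct <- diary$contacts[which(keep)[sel], , drop = FALSE]
  cg <- cg[sel]
  pidx <- match(ct$participant_id, diary$participants$participant_id)
  tab <- table(factor(pidx, levels = seq_len(nrow(diary$participants))), cg)
  Xp <- matrix(as.numeric(tab), nrow = nrow(diary$participants),
               dimnames = list(diary$participants$participant_id, groups))
  list(Xp = Xp, part_group = part_group, groups = groups,
       n_days = n_days, n_excluded = n_excluded)
}

matrix_from_tallies <- function(pm, idx = NULL) {
  part <- pm$part_group
  Xp <- pm$Xp
  if (!is.null(idx)) {
    part <- part[idx]
    Xp <- Xp[idx, , drop = FALSE]
  }
  g <- table(part)
  if (any(g == 0)) {
    return(list(m = NULL, g = g, empty = names(g)[g == 0]))
  }
  x <- rowsum(Xp, part)                      # groups_j x groups_i
  m <- t(sweep(x, 1, as.numeric(g) * pm$n_days, "/"))  # rows i, cols j
  dimnames(m) <- list(pm$groups, pm$groups)
  list(m = m, g = g, empty = character())
}

stratum_info <- function(diary, period, location) {
  if (!is.null(period) && !is.null(location)) {
    rlang::abort("stratify by period or location, not both",
                 class = "contactdiaries_validation_error")
  }
  days <- diary$calendar$days
  if (!is.null(period)) {
    stopifnot(period %in% period_levels())
    keep <- classify_period(diary$contacts$date, diary$calendar) == period
    list(keep = keep, n_days = sum(days$period == period),
         stratum = paste0("period:", period))
  } else if (!is.null(location)) {
    if (!location %in% location_levels()) {
      rlang::abort(paste0("unknown location: ", location),
                   class = "contactdiaries_validation_error")
    }
    # location matrices ignore the contact date: all diary days normalise
    list(keep = diary$contacts$location == location, n_days = nrow(days),
         stratum = paste0("location:", location))
  } else {
    list(keep = rep(TRUE, nrow(diary$contacts)), n_days = nrow(days),
         stratum = "all")
  }
}

#' Raw age-grouped contact matrix
#'
#' `m[i, j] = x[i, j] / (g[j] * d)`: total contacts reported by
#' participants in age group `j` with persons in age group `i`, divided by
#' the number of participants in group `j` and the number of stratum days
#' `d`, so every matrix is in contacts per participant per day. Rows index
#' the contact person's group, columns the participant's group. Contacts
#' with unknown age are excluded (their count is attached as attribute
#' `n_excluded`).
#'
#' @param diary A [survey_diary()].
#' @param breaks Age-bin lower edges.
#' @param period Optional single period label restricting the records.
#' @param location Optional single location label (all days normalise).
#' @return List with elements `m` (matrix), `g` (participants per group),
#'   `n_days`, `stratum`.
#' @export
raw_matrix <- function(diary, breaks = age_breaks_analysis(),
                       period = NULL, location = NULL) {
  st <- stratum_info(diary, period, location)
  part_group <- age_bin(diary$participants$age_years, breaks)
  part_group <- factor(as.character(part_group), levels = age_bin_labels(breaks))
  contact_group <- age_bin(diary$contacts$contact_age_years, breaks)
  contact_group <- factor(as.character(contact_group),
                          levels = age_bin_labels(breaks))
  pm <- prep_matrix_data(diary, part_group, contact_group, st$keep, st$n_days)
  res <- matrix_from_tallies(pm)
  if (is.null(res$m)) {
    rlang::abort(paste0("empty participant age group(s): ",
                        paste(res$empty, collapse = ", ")),
                 class = "contactdiaries_validation_error")
  }
  out <- list(m = res$m, g = res$g, n_days = pm$n_days, stratum = st$stratum)
  attr(out, "n_excluded") <- pm$n_excluded
  out
}

#' Reciprocity correction of a contact matrix
#'
#' At the population level the total number of contacts from group `j` to
#' group `i` must equal the reverse flow: `m[i,j] G[j] = m[j,i] G[i]`. The
#' corrected matrix averages the two flows,
#' `C[i,j] = (m[i,j] G[j] + m[j,i] G[i]) / 2` and `mC[i,j] = C[i,j] / G[j]`,
#' and satisfies reciprocity exactly. The operation is linear in `m`,
#' idempotent, and conserves the population-level total number of contacts.
#'
#' @param m Square non-negative matrix, rows = contact group, columns =
#'   participant group.
#' @param G Positive population sizes per group.
#' @return Corrected matrix of the same dimensions.
#' @export
reciprocity_correct <- function(m, G) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), length(G) == ncol(m))
  if (any(G <= 0)) {
    rlang::abort("population sizes must be positive",
                 class = "contactdiaries_validation_error")
  }
  # the correction depends on G only through ratios; normalising keeps the
  # flow arithmetic at O(m) magnitude so reciprocity holds to ~1e-15
  w <- as.numeric(G) / mean(as.numeric(G))
  flow <- sweep(m, 2, w, "*")          # m_ij G_j (scale-free)
  C <- (flow + t(flow)) / 2
  sweep(C, 2, w, "/")
}

boot_population <- function(diary, groups) {
  pop <- diary$population
  G <- pop$count[match(groups, pop$age_bin)]
  if (anyNA(G)) {
    rlang::abort(paste0("population table lacks group(s): ",
                        paste(groups[is.na(G)], collapse = ", ")),
                 class = "contactdiaries_validation_error")
  }
  stats::setNames(as.numeric(G), groups)
}

bootstrap_core <- function(pm, B, seed, correct, G, stratum) {
  set.seed(seed)
  base <- matrix_from_tallies(pm)
  if (is.null(base$m)) {
    rlang::abort(paste0("empty participant group(s): ",
                        paste(base$empty, collapse = ", ")),
                 class = "contactdiaries_validation_error")
  }
  point <- if (correct) reciprocity_correct(base$m, G) else base$m
  n <- nrow(pm$Xp)
  k <- length(pm$groups)
  reps <- array(NA_real_, c(k, k, B))
  attempts <- 0L
  b <- 1L
  redrawn <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 100L * B) {
      rlang::abort(
        "bootstrap exhausted redraw budget: replicates keep producing empty groups",
        class = "contactdiaries_bootstrap_error")
    }
    idx <- sample.int(n, n, replace = TRUE)
    res <- matrix_from_tallies(pm, idx)
    if (is.null(res$m)) {
      redrawn <- redrawn + 1L
      next
    }
    reps[, , b] <- if (correct) reciprocity_correct(res$m, G) else res$m
    b <- b + 1L
  }
  if (redrawn > 0L) {
    rlang::warn(paste0(redrawn, " bootstrap replicate(s) redrawn because of ",
                       "empty participant groups"))
  }
  boot_mean <- apply(reps, c(1, 2), mean)
  ci_low <- apply(reps, c(1, 2), stats::quantile, 0.025)
  ci_high <- apply(reps, c(1, 2), stats::quantile, 0.975)
  dimnames(boot_mean) <- dimnames(ci_low) <- dimnames(ci_high) <-
    dimnames(point)
  structure(
    list(bins = pm$groups, point = point, boot_mean = boot_mean,
         ci_low = ci_low, ci_high = ci_high,
         g = stats::setNames(as.numeric(base$g), pm$groups), G = G,
         stratum = stratum, corrected = correct, B = B, seed = seed,
         n_days = pm$n_days, n_excluded = pm$n_excluded),
    class = "contact_matrix")
}

#' Bootstrapped age-grouped contact matrix
#'
#' Participants are resampled with replacement (each carrying all of their
#' diary days and contact records — the participant is the sampling unit of
#' a clustered diary design), the (optionally reciprocity-corrected) matrix
#' is recomputed per replicate, and the elementwise mean and central 95%
#' percentile interval are reported. The default of 2000 replicates matches
#' the study design. Replicates in which an age group loses all its
#' participants are redrawn, up to a capped budget.
#'
#' @inheritParams raw_matrix
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param correct Apply [reciprocity_correct()] with the diary's population
#'   counts.
#' @param G Optional population vector overriding the diary's table.
#' @return A `contact_matrix` object: point and bootstrap-mean matrices, CI
#'   matrices, participant counts `g`, population `G`, and stratum metadata.
#' @export
bootstrap_matrix <- function(diary, breaks = age_breaks_analysis(),
                             period = NULL, location = NULL,
                             B = 2000L, seed = 1L, correct = TRUE,
                             G = NULL) {
  stopifnot(B >= 1L)
  st <- stratum_info(diary, period, location)
  labels <- age_bin_labels(breaks)
  part_group <- factor(as.character(age_bin(diary$participants$age_years,
                                            breaks)), levels = labels)
  contact_group <- factor(
    as.character(age_bin(diary$contacts$contact_age_years, breaks)),
    levels = labels)
  pm <- prep_matrix_data(diary, part_group, contact_group, st$keep, st$n_days)
  if (is.null(G)) {
    G <- if (correct) {
      boot_population(diary, labels)
    } else {
      # population sizes are only needed for the correction; fall back to the
      # participant counts as nominal weights when the table lacks the bins
      tryCatch(boot_population(diary, labels),
               error = function(e) table(part_group))
    }
  }
  bootstrap_core(pm, B, seed, correct, G, st$stratum)
}

#' Bootstrapped residential-region contact matrix
#'
#' Like [bootstrap_matrix()] but grouped by the residential region of
#' participants and contact persons (rows = contact's region), at the
#' 17-province or 5-major-region level. Contacts whose region is unknown are
#' excluded before normalisation. Population sizes per region default to the
#' total diary population allocated by the participants' region shares
#' (quota sampling matches the regional margins); pass `G` to override.
#'
#' @inheritParams bootstrap_matrix
#' @param level `"5"` (major regions) or `"17"` (provinces).
#' @return A `contact_matrix` object over region groups.
#' @export
region_matrix <- function(diary, level = c("5", "17"), period = NULL,
                          B = 2000L, seed = 1L, correct = TRUE, G = NULL) {
  level <- match.arg(level)
  st <- stratum_info(diary, period, NULL)
  unk <- unknown_label()
  if (level == "5") {
    labels <- region5_levels()
    part_g <- factor(diary$participants$region5, levels = labels)
    creg <- region5_of(diary$contacts$contact_region17)
  } else {
    labels <- region17_levels()
    part_g <- factor(diary$participants$region17, levels = labels)
    creg <- diary$contacts$contact_region17
  }
  contact_g <- factor(ifelse(creg == unk, NA_character_, creg),
                      levels = labels)
  pm <- prep_matrix_data(diary, part_g, contact_g, st$keep, st$n_days)
  if (is.null(G)) {
    shares <- prop.table(table(part_g))
    G <- stats::setNames(as.numeric(shares) * sum(diary$population$count),
                         labels)
  }
  bootstrap_core(pm, B, seed, correct, G, st$stratum)
}

#' Bootstrapped location-specific contact matrix
#'
#' Age-grouped matrix restricted to contacts at one location, normalised
#' over all diary days (the contact date is not part of the stratum).
#'
#' @inheritParams bootstrap_matrix
#' @param location One of the schema location levels.
#' @return A `contact_matrix` object.
#' @export
location_matrix <- function(diary, location, breaks = age_breaks_analysis(),
                            B = 2000L, seed = 1L, correct = TRUE, G = NULL) {
  bootstrap_matrix(diary, breaks = breaks, location = location,
                   B = B, seed = seed, correct = correct, G = G)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix>", length(x$bins), "x", length(x$bins),
      "groups, stratum:", x$stratum,
      if (x$corrected) "(reciprocity-corrected)" else "(raw)", "\n")
  cat("  bootstrap B =", x$B, "\n")
  print(round(x$boot_mean, 2))
  invisible(x)
}

#' Tidy a bootstrapped contact matrix into long format
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `stratum`, `contact_group`,
#'   `participant_group`, `point`, `boot_mean`, `conf_low`, `conf_high`.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  grid <- tidyr::expand_grid(
    participant_group = factor(x$bins, levels = x$bins),
    contact_group = factor(x$bins, levels = x$bins))
  grid |>
    dplyr::mutate(
      stratum = x$stratum,
      point = as.numeric(x$point[cbind(as.integer(.data$contact_group),
                                       as.integer(.data$participant_group))]),
      boot_mean = as.numeric(x$boot_mean[cbind(as.integer(.data$contact_group),
                                               as.integer(.data$participant_group))]),
      conf_low = as.numeric(x$ci_low[cbind(as.integer(.data$contact_group),
                                           as.integer(.data$participant_group))]),
      conf_high = as.numeric(x$ci_high[cbind(as.integer(.data$contact_group),
                                             as.integer(.data$participant_group))])) |>
    dplyr::relocate("stratum")
}
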