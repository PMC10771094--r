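#' Consistency of the three control periods
#'
#' One-way repeated-factor ANOVA of per-bat tau-quantile distances across
#' the three control periods, with bat as the blocking factor. A
#' non-significant period effect justifies using the first control period as
#' the baseline for the treatment comparisons.
#'
#' @param pq Per-bat period quantiles from [period_quantiles()].
#' @param tau Quantile level to test.
#' @return Tibble (class `ud_anova_table`): `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, rows `period`, `bat`, `Residuals`. Degenerate
#'   zero-variance cases are reported as `F = 0`, `p = 1`.
#' @export
control_consistency <- function(pq, tau) {
  dat <- pq |>
    filter(.data$tau == !!tau,
           .data$period_label %in% c("control1", "control2", "control3"),
           !is.na(.data$value)) |>
    select("bat_id", "period_label", "value")
  complete <- dat |>
    count(.data$bat_id) |>
    filter(.data$n == 3) |>
    pull(.data$bat_id)
  dat <- filter(dat, .data$bat_id %in% complete)
  if (length(complete) < 2) abort("need >= 2 bats with all three controls")
  fit <- aov(value ~ bat_id + period_label, data = dat)
  tab <- summary(fit)[[1]]
  out <- tibble(
    term = c("bat", "period", "Residuals"),
    df = tab$Df[c(1, 2, 3)],
    sumsq = tab$`Sum Sq`[c(1, 2, 3)],
    meansq = tab$`Mean Sq`[c(1, 2, 3)],
    statistic = c(tab$`F value`[1:2], NA_real_),
    p.value = c(tab$`Pr(>F)`[1:2], NA_real_)
  )
  patch_degenerate_f(out)
}

# 0/0 F ratios (no between- and no residual variance) are reported as
# F = 0, p = 1: identical data carry no evidence of a difference.
patch_degenerate_f <- function(tab, eps = 1e-10) {
  deg <- !is.na(tab$statistic) & (tab$sumsq < eps | is.nan(tab$statistic))
  tab$statistic[deg] <- 0
  tab$p.value[deg] <- 1
  tab
}

#' Sex / season factorial ANOVA on per-bat treatment effects
#'
#' Two-way ANOVA (Type II sums of squares, appropriate for the unbalanced
#' sex-by-season designs) on per-bat treatment-minus-control quantile
#' differences, with Tukey HSD pairwise contrasts for each factor and, when
#' the interaction is estimable, for the four sex-by-season cells.
#'
#' The interaction term is included only when all four cells contain data:
#' species lacking a cell (for example no spring females) are fit with main
#' effects only, and requesting the interaction anyway is an error naming
#' the empty cell.
#'
#' @param effects Tibble with one row per bat: `bat_id`, `sex`, `season`,
#'   `effect` (meters).
#' @param include_interaction `TRUE`, `FALSE`, or `NULL` to decide from cell
#'   occupancy.
#' @return Object of class `ud_anova`: list with `anova` (term table),
#'   `contrasts` (`factor`, `group_a`, `group_b`, `difference_m`,
#'   `p_adjusted`, oriented so `difference_m >= 0` means `group_a` >
#'   `group_b`), `n_bats`, `interaction`.
#' @export
group_anova <- function(effects, include_interaction = NULL) {
  stopifnot(all(c("bat_id", "sex", "season", "effect") %in% names(effects)))
  dat <- effects |>
    filter(!is.na(.data$effect)) |>
    mutate(sex = factor(.data$sex, c("F", "M")),
           season = factor(.data$season, c("fall", "spring")))
  cells <- with(dat, table(sex, season))
  empty <- which(cells == 0, arr.ind = TRUE)
  all_cells <- nrow(empty) == 0
  if (isTRUE(include_interaction) && !all_cells) {
    abort(sprintf("cannot include sex:season interaction: cell %s x %s is empty",
                  rownames(cells)[empty[1, 1]], colnames(cells)[empty[1, 2]]),
          class = "batcage_config_error")
  }
  use_int <- include_interaction %||% all_cells
  form <- if (use_int) effect ~ sex * season else effect ~ sex + season
  if (stats::var(dat$effect) < 1e-20) {
    # no variation at all: nothing to partition
    trms <- c("sex", "season", if (use_int) "sex:season", "Residuals")
    tab <- tibble(term = trms,
                  df = c(rep(1L, length(trms) - 1),
                         nrow(dat) - length(trms) + 1L),
                  sumsq = 0, meansq = 0,
                  statistic = c(rep(0, length(trms) - 1), NA_real_),
                  p.value = c(rep(1, length(trms) - 1), NA_real_))
  } else {
    fit <- lm(form, data = dat)
    a2 <- car::Anova(fit, type = 2)
    tab <- tibble(
      term = rownames(a2),
      df = a2$Df,
      sumsq = a2$`Sum Sq`,
      meansq = a2$`Sum Sq` / a2$Df,
      statistic = a2$`F value`,
      p.value = a2$`Pr(>F)`
    )
    tab <- patch_degenerate_f(tab)
  }

  contr <- list(
    tukey_contrasts(dat, "sex"),
    tukey_contrasts(dat, "season")
  )
  if (use_int) {
    dat$cell <- factor(paste(dat$sex, dat$season))
    contr <- c(contr, list(tukey_contrasts(dat, "cell",
                                           label = "sex:season")))
  }
  structure(
    list(anova = tab, contrasts = bind_rows(contr),
         n_bats = nrow(dat), interaction = use_int),
    class = "ud_anova"
  )
}

# Tukey honest-significant-difference contrasts of cell means for one factor,
# oriented so the larger-mean group comes first.
tukey_contrasts <- function(dat, var, label = var) {
  if (nlevels(droplevels(dat[[var]])) < 2) return(NULL)
  dat$g <- droplevels(dat[[var]])
  if (sd(dat$effect) < 1e-12) {
    # all-equal responses: no contrasts distinguishable
    cmb <- utils::combn(levels(dat$g), 2)
    return(tibble(factor = label, group_a = cmb[2, ], group_b = cmb[1, ],
                  difference_m = 0, p_adjusted = 1))
  }
  hsd <- TukeyHSD(aov(effect ~ g, data = dat))$g
  nm <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble(
    factor = label,
    group_a = vapply(nm, `[`, "", 1),
    group_b = vapply(nm, `[`, "", 2),
    difference_m = unname(hsd[, "diff"]),
    p_adjusted = unname(hsd[, "p adj"])
  ) |>
    mutate(
      swap = .data$difference_m < 0,
      ga = if_else(.data$swap, .data$group_b, .data$group_a),
      gb = if_else(.data$swap, .data$group_a, .data$group_b),
      difference_m = abs(.data$difference_m)
    ) |>
    select("factor", group_a = "ga", group_b = "gb", "difference_m",
           "p_adjusted")
}

#' @export
print.ud_anova <- function(x, ...) {
  cat(sprintf("<ud_anova> %d bats, interaction %s\n", x$n_bats,
              if (x$interaction) "included" else "excluded"))
  print(x$anova)
  cat("Pairwise (Tukey HSD):\n")
  print(x$contrasts)
  invisible(x)
}

#' Per-bat quantile treatment differences for one treatment and tau
#'
#' Convenience builder for [group_anova()]: joins per-bat quantile
#' differences (treatment minus first control) with bat metadata.
#'
#' @param pq Per-bat period quantiles from [period_quantiles()].
#' @param metadata Tibble `bat_id`, `sex`, `season` (plus anything else).
#' @param treatment,tau Cell to extract.
#' @param control Baseline period label.
#' @return Tibble `bat_id`, `sex`, `season`, `effect`.
#' @export
bat_effects <- function(pq, metadata, treatment, tau,
                        control = "control1") {
  qt <- pq |>
    filter(.data$tau == !!tau,
           .data$period_label %in% c(!!treatment, !!control)) |>
    select("bat_id", "period_label", "value") |>
    tidyr::pivot_wider(names_from = "period_label", values_from = "value")
  qt$effect <- qt[[treatment]] - qt[[control]]
  qt |>
    inner_join(select(metadata, "bat_id", "sex", "season"), by = "bat_id") |>
    select("bat_id", "sex", "season", "effect") |>
    filter(!is.na(.data$effect))
}
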