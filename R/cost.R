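## Kit-economics: cost per reaction from minimum orderable kit sizes.

#' Cost specification for a genotyping platform
#'
#' Prices and reaction counts for the minimum orderable amount of the two
#' consumables (allele-specific assay mix and master mix).
#'
#' @param platform_id Platform name.
#' @param assay_price Price of the minimum assay-mix order (currency,
#'   >= 0).
#' @param assay_reactions Reactions the assay-mix order supports (> 0).
#' @param mastermix_price Price of the minimum master-mix order (>= 0).
#' @param mastermix_reactions Reactions the master-mix order supports
#'   (> 0).
#' @param reaction_volume_ul Reaction volume in microlitres (metadata;
#'   default 5).
#' @return An object of class \code{"cost_spec"}.
#' @export
cost_spec <- function(platform_id, assay_price, assay_reactions,
                      mastermix_price, mastermix_reactions,
                      reaction_volume_ul = 5) {
  stopifnot(is.character(platform_id), length(platform_id) == 1L,
            assay_price >= 0, mastermix_price >= 0,
            reaction_volume_ul > 0)
  if (assay_reactions <= 0 || mastermix_reactions <= 0)
    stop("reaction counts must be positive", call. = FALSE)
  structure(list(platform_id = platform_id,
                 assay_price = assay_price,
                 assay_reactions = as.integer(assay_reactions),
                 mastermix_price = mastermix_price,
                 mastermix_reactions = as.integer(mastermix_reactions),
                 reaction_volume_ul = reaction_volume_ul),
            class = "cost_spec")
}

#' Reference cost specifications for TaqMan, KASP and rhAmp
#'
#' List prices for the minimum orderable assay-mix and master-mix kit of
#' each chemistry, at a 5 ul reaction volume: TaqMan assay mix $259 /
#' 2,000 reactions with $554 / 2,000-reaction master mix; KASP $64.2 /
#' 5,000 with $1,382.5 / 10,000; rhAmp $75.6 / 5,000 with $1,038.6 /
#' 10,000.  DNA-extraction cost is excluded.
#'
#' @return Named list of three [cost_spec()] objects.
#' @export
default_cost_specs <- function() {
  list(
    TaqMan = cost_spec("TaqMan", 259, 2000, 554, 2000),
    KASP = cost_spec("KASP", 64.2, 5000, 1382.5, 10000),
    rhAmp = cost_spec("rhAmp", 75.6, 5000, 1038.6, 10000))
}

## round half-up to cents (commercial rounding, not banker's)
.round_cents <- function(x) floor(x * 100 + 0.5) / 100

#' Cost per reaction
#'
#' Divides each consumable's price by the number of reactions its minimum
#' order supports and sums:
#' \code{assay_price/assay_reactions + mastermix_price/mastermix_reactions}.
#' Returned both raw and rounded half-up to the cent.
#'
#' @param spec A [cost_spec()] object.
#' @return List with \code{platform_id}, \code{raw} and \code{rounded}.
#' @examples
#' cost_per_reaction(default_cost_specs()$TaqMan)$rounded  # 0.41
#' @export
cost_per_reaction <- function(spec) {
  stopifnot(inherits(spec, "cost_spec"))
  raw <- spec$assay_price / spec$assay_reactions +
    spec$mastermix_price / spec$mastermix_reactions
  list(platform_id = spec$platform_id, raw = raw,
       rounded = .round_cents(raw))
}

#' Rank platforms by per-reaction cost
#'
#' Stable ascending sort on the raw (unrounded) per-reaction cost; ties
#' keep input order.
#'
#' @param specs List of [cost_spec()] objects.
#' @return Data frame (cheapest first) with \code{platform_id},
#'   \code{cost_raw}, \code{cost_rounded}.
#' @examples
#' rank_platforms(default_cost_specs())
#' @export
rank_platforms <- function(specs) {
  if (inherits(specs, "cost_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  costs <- lapply(specs, cost_per_reaction)
  out <- data.frame(
    platform_id = vapply(costs, `[[`, "", "platform_id"),
    cost_raw = vapply(costs, `[[`, 0, "raw"),
    cost_rounded = vapply(costs, `[[`, 0, "rounded"),
    stringsAsFactors = FALSE)
  out <- out[order(out$cost_raw), , drop = FALSE]   # order() is stable
  rownames(out) <- NULL
  out
}

#' Read cost specifications from CSV
#'
#' Expects columns \code{platform_id, assay_price, assay_reactions,
#' mastermix_price, mastermix_reactions} and optionally
#' \code{reaction_volume_ul}.
#'
#' @param path CSV path.
#' @return Named list of [cost_spec()] objects.
#' @export
read_cost_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("platform_id", "assay_price", "assay_reactions",
            "mastermix_price", "mastermix_reactions")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stop_format("cost file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", "))
  specs <- lapply(seq_len(nrow(df)), function(i)
    cost_spec(df$platform_id[i], df$assay_price[i],
              df$assay_reactions[i], df$mastermix_price[i],
              df$mastermix_reactions[i],
              if ("reaction_volume_ul" %in% names(df))
                df$reaction_volume_ul[i] else 5))
  stats::setNames(specs, df$platform_id)
}
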