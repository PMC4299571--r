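#' Currency conversion table
#'
#' Conversion settings for expressing costs in constant 2013 international
#' dollars: a consumer-price-index deflator per calendar year (multiplier
#' taking that year's Malawi Kwacha to 2013 Kwacha), the purchasing-power
#' parity factor (Kwacha per 2013 international dollar), and optional
#' year-specific exchange rates (Kwacha per pound / per US dollar) for
#' costs incurred in GBP or USD.
#'
#' @param ppp_mwk_per_intl Kwacha per 2013 international dollar
#'   (default 105.8).
#' @param cpi_deflator Named numeric vector, names = calendar years,
#'   values = multiplier to 2013 local prices. The default carries only
#'   2013 = 1; supply the deflators your ledger needs.
#' @param gbp_mwk,usd_mwk Named numeric vectors of year-specific exchange
#'   rates (MWK per GBP / per USD).
#'
#' @return An object of class `currency_table`.
#' @export
#' @examples
#' tab <- currency_table()
#' convert_to_intl2013(105.8, "MWK", 2013, tab) # 1 international dollar
currency_table <- function(ppp_mwk_per_intl = 105.8,
                           cpi_deflator = c("2013" = 1),
                           gbp_mwk = NULL,
                           usd_mwk = NULL) {
  if (!is.finite(ppp_mwk_per_intl) || ppp_mwk_per_intl <= 0) {
    stop("'ppp_mwk_per_intl' must be positive", call. = FALSE)
  }
  if (any(cpi_deflator <= 0)) {
    stop("all CPI deflators must be positive", call. = FALSE)
  }
  structure(list(ppp_mwk_per_intl = ppp_mwk_per_intl,
                 cpi_deflator = cpi_deflator,
                 gbp_mwk = gbp_mwk,
                 usd_mwk = usd_mwk),
            class = "currency_table")
}

year_rate <- function(rates, year, what) {
  key <- as.character(year)
  if (is.null(rates) || !key %in% names(rates)) {
    stop(sprintf("currency table has no %s for year %s", what, key),
         call. = FALSE)
  }
  rates[[key]]
}

#' Convert an amount to constant 2013 international dollars
#'
#' Kwacha amounts are deflated to 2013 local prices with the CPI and divided
#' by the PPP factor. GBP/USD amounts are first converted to Kwacha at the
#' configured year-specific exchange rate, then treated the same way.
#' Amounts already in 2013 international dollars pass through unchanged.
#'
#' @param amount Amount in `currency`.
#' @param currency One of `"MWK"`, `"GBP"`, `"USD"`, `"INTL2013"`.
#' @param year Calendar year the cost was incurred.
#' @param table A [currency_table()].
#' @return Amount in constant 2013 international $.
#' @export
convert_to_intl2013 <- function(amount, currency, year,
                                table = currency_table()) {
  stopifnot(inherits(table, "currency_table"))
  currency <- toupper(currency)
  if (currency == "INTL2013") return(amount)
  mwk <- switch(currency,
    MWK = amount,
    GBP = amount * year_rate(table$gbp_mwk, year, "GBP rate"),
    USD = amount * year_rate(table$usd_mwk, year, "USD rate"),
    stop("unknown currency: ", currency, call. = FALSE)
  )
  mwk * year_rate(table$cpi_deflator, year, "CPI deflator") /
    table$ppp_mwk_per_intl
}

#' Convert 2013 international dollars back to Kwacha of a given year
#'
#' Inverse of the MWK path of [convert_to_intl2013()]; useful for checking
#' conversions round-trip.
#'
#' @inheritParams convert_to_intl2013
#' @param amount Amount in 2013 international $.
#' @return Amount in MWK of `year`.
#' @export
intl2013_to_mwk <- function(amount, year, table = currency_table()) {
  stopifnot(inherits(table, "currency_table"))
  amount * table$ppp_mwk_per_intl /
    year_rate(table$cpi_deflator, year, "CPI deflator")
}
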