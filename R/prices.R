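#' Vendor price quotes
#'
#' Retail prices are recorded from local vendors in rupees per kilogram;
#' the arithmetic mean across vendors is the price used for linear
#' programming.
#'
#' `mean_price()` averages one food's quotes. `read_prices()` reads a CSV
#' with a `food_id` column followed by one column per vendor quote
#' (`vendor1`, `vendor2`, ...; a missing quote is left empty) and returns a
#' tibble with `food_id`, a `vendor_quotes` list-column and `mean_price`.
#'
#' @param quotes Numeric vector of quotes, all positive, length >= 1.
#' @return `mean_price()`: a single numeric, rupees/kg.
#' @export
#' @examples
#' mean_price(c(20, 30, 40)) # 30
mean_price <- function(quotes) {
  if (length(quotes) == 0) abort("At least one vendor quote is required.")
  if (any(!is.finite(quotes) | quotes <= 0)) {
    abort("All vendor quotes must be finite and > 0 (rupees/kg).")
  }
  mean(quotes)
}

#' @rdname mean_price
#' @param path Path to a prices CSV file.
#' @export
read_prices <- function(path) {
  if (!file.exists(path)) abort(sprintf("Prices file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"food_id" %in% names(df)) abort("Prices CSV needs a food_id column.")
  vcols <- grep("^vendor", names(df), value = TRUE)
  if (length(vcols) == 0) {
    abort("Prices CSV needs at least one vendor* column.")
  }
  if (anyDuplicated(df$food_id)) {
    abort("Duplicate food_id in prices CSV.")
  }
  quotes <- map(seq_len(nrow(df)), function(i) {
    q <- as.numeric(df[i, vcols])
    q[!is.na(q)]
  })
  tibble(
    food_id = df$food_id,
    vendor_quotes = quotes,
    mean_price = map_dbl(quotes, mean_price)
  )
}

#' @rdname mean_price
#' @param prices A prices tibble as returned by `read_prices()`.
#' @export
write_prices <- function(prices, path) {
  stopifnot(all(c("food_id", "vendor_quotes") %in% names(prices)))
  k <- max(lengths(prices$vendor_quotes))
  wide <- map(prices$vendor_quotes, function(q) {
    as_tibble(as.list(setNames(c(q, rep(NA_real_, k - length(q))),
                               paste0("vendor", seq_len(k)))))
  }) |>
    list_rbind()
  readr::write_csv(bind_cols(tibble(food_id = prices$food_id), wide), path,
                   progress = FALSE)
  invisible(path)
}
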