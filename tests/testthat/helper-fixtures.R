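# Fixtures built in code: a small deterministic candidate pool plus random
# table generators for property-style tests.

toy_countries <- function() {
  suppressMessages(country_table(data.frame(
    country_id = c("ATL", "BRV", "CRL", "DLT", "EST"),
    name = paste("Country", 1:5),
    debt_to_gdp = c(0.35, 0.55, 0.65, 0.85, 1.05),
    eez_area_km2 = c(5e5, 3e5, 1.2e6, 8e4, 2e5),
    coral_area_km2 = c(1200, 0, 300, 4500, 800),
    sovereign = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)))
}

toy_layers <- function() {
  m <- rbind(
    ATL = c(0.20, 0.40, 0.10, 0.70, 0.60),
    BRV = c(0.50, 0.10, 0.30, 0.80, 0.75),
    CRL = c(0.10, 0.20, 0.05, 0.60, 0.55),
    DLT = c(0.60, 0.55, 0.40, 0.90, 0.85),
    EST = c(0.30, 0.30, 0.20, 0.75, 0.70))
  colnames(m) <- c("trawling", "artisanal", "shipping", "heat_stress", "acidification")
  threat_table(m)
}

toy_schemes <- function() {
  base <- c(trawling = "abatable", artisanal = "abatable", shipping = "abatable",
            heat_stress = "unabatable", acidification = "unabatable")
  alt <- base
  alt["shipping"] <- "unabatable"
  list(A = classification_scheme("A", base),
       B = classification_scheme("B", alt))
}

# Random country table with uniform debt ratios and log-normal areas.
random_countries <- function(n, extra_flags = FALSE) {
  df <- data.frame(
    country_id = sprintf("R%03d", seq_len(n)),
    debt_to_gdp = stats::runif(n, 0, 1.3),
    eez_area_km2 = stats::rlnorm(n, 11, 1.5),
    coral_area_km2 = stats::rlnorm(n, 5, 1.5),
    p_success = stats::runif(n, 0.2, 1),
    cost = stats::runif(n, 0.5, 5),
    stringsAsFactors = FALSE)
  if (extra_flags) df$sovereign <- stats::runif(n) < 0.8
  suppressMessages(country_table(df))
}

# Random complete threat table over n countries x p layers.
random_layers <- function(ids, p = 6) {
  m <- matrix(stats::runif(length(ids) * p), length(ids), p,
              dimnames = list(ids, sprintf("layer%02d", seq_len(p))))
  threat_table(m)
}

random_scheme <- function(layers, id = "rand") {
  p <- length(layers$layer_names)
  cls <- rep("abatable", p)
  cls[sample.int(p, max(1L, sample.int(p - 1L, 1L)))] <- "unabatable"
  if (!"abatable" %in% cls) cls[1L] <- "abatable"
  classification_scheme(id, stats::setNames(cls, layers$layer_names))
}

fixed_alpha <- function(value) {
  structure(list(value = value, policy = "fixed", pool_id = "test",
                 max_iu = if (value > 0) 1 / value else Inf),
            class = "alpha_parameter")
}
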