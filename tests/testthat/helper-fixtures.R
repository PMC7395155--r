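# Shared fixtures built in code.

# minimal valid sightings table
make_sightings <- function(n = 3, perp = seq(0.2, by = 0.5, length.out = n),
                           sizes = rep(2L, n)) {
  data.frame(
    perp_distance = perp,
    group_size = sizes,
    species = "humpback",
    beaufort = rep(1L, n),
    visibility = rep("Good", n),
    sightability = rep(0L, n),
    stringsAsFactors = FALSE
  )
}

# FOI table from a matrix of psi scores (rows = FOIs)
make_foi <- function(psi, sea_state = "good", stratum = "calmer",
                     observer = "O1") {
  psi <- matrix(as.integer(psi), ncol = 13)
  df <- data.frame(foi_id = sprintf("F%03d", seq_len(nrow(psi))),
                   stringsAsFactors = FALSE)
  df[paste0("psi", 1:13)] <- as.data.frame(psi)
  df$sea_state <- rep_len(sea_state, nrow(psi))
  df$stratum <- rep_len(stratum, nrow(psi))
  df$observer <- rep_len(observer, nrow(psi))
  validate_foi_table(df)
}

# psi vector with named criteria set
psi_vec <- function(...) {
  v <- rep(0L, 13)
  set <- list(...)
  for (nm in names(set)) v[as.integer(sub("psi", "", nm))] <- set[[nm]]
  v
}

# a detection_fit object with known parameters (no fitting)
make_hn_fit <- function(sigma, w, distances = numeric(0)) {
  mu <- sigma * sqrt(2 * pi) * (pnorm(w / sigma) - 0.5)
  structure(list(
    key = "hn", covariate_formula = character(0),
    scale_params = c("(Intercept)" = log(sigma)), shape_param = NULL,
    sigma = sigma, truncation_w = w, n = length(distances),
    P_a_hat = mu / w, se_P_a = NA_real_, esw = mu,
    log_lik = NA_real_, k = 1L, AIC = NA_real_,
    distances = distances, Z = matrix(numeric(0), length(distances), 0)
  ), class = "detection_fit")
}

# draw n half-normal distances truncated at w
rhn <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(rnorm(2 * n, 0, sigma))
    out <- c(out, x[x <= w])
  }
  out[seq_len(n)]
}
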