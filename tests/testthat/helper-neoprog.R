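# Independent brute-force oracle for the localisation degree: explicitly
# bins each delayed value against the eight interval bounds (left-closed,
# last right-closed) instead of arithmetic index computation.
brute_force_ld <- function(all_values, delayed_values) {
  all_values <- all_values[!is.na(all_values)]
  delayed_values <- delayed_values[!is.na(delayed_values)]
  lo <- min(all_values)
  hi <- max(all_values)
  bounds <- lo + (0:8) * (hi - lo) / 8
  occupied <- logical(8)
  for (d in delayed_values) {
    for (j in 1:8) {
      in_j <- (d >= bounds[j] && d < bounds[j + 1]) ||
        (j == 8L && d == bounds[9])
      if (in_j) occupied[j] <- TRUE
    }
  }
  sum(occupied) / 8
}

# Hand-built selection result, for stages that only need the chosen
# characteristic lists (zone fitting, ensemble training).
fake_selection <- function(inner, selected = inner) {
  structure(list(profiles = data.frame(characteristic = selected,
                                       ld = rep(NA_real_, length(selected)),
                                       stringsAsFactors = FALSE),
                 ranked = selected, selected = selected,
                 inner_subset = inner, ld_threshold = 0.375,
                 inner_size = length(inner)),
            class = "selection_result")
}

# Class distribution with the delayed mean shifted by `shift` pooled SDs on
# the given characteristics (equal class SDs there), otherwise the motor
# defaults.
shifted_distribution <- function(chars, shift = 2) {
  d <- default_class_distribution("motor")
  i <- match(chars, d$characteristic)
  stopifnot(!anyNA(i))
  d$sd_delayed[i] <- d$sd_normal[i]
  d$mean_delayed[i] <- d$mean_normal[i] + shift * d$sd_normal[i]
  d
}

# Small linearly separable two-class table over the given inner columns:
# delayed at +margin, normal at -margin (in SD units), tiny within-class
# noise.
separable_members <- function(n_normal, n_delayed, inner, margin = 4,
                              seed = 1) {
  set.seed(seed)
  n <- n_normal + n_delayed
  lab <- c(rep(0L, n_normal), rep(1L, n_delayed))
  tab <- data.frame(subject_id = sprintf("M%03d", seq_len(n)),
                    label = lab, severe_injury = 0L,
                    stringsAsFactors = FALSE)
  for (id in inner)
    tab[[id]] <- ifelse(lab == 1L, margin, -margin) + stats::rnorm(n, 0, 0.5)
  tab
}
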