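# Independent brute-force oracle for the vial-rounding cost: depth-first
# search over all covering combinations, pruned on cost.
brute_vial_cost <- function(dose, vials) {
  best <- Inf
  n <- nrow(vials)
  rec <- function(i, mg, cost) {
    if (cost >= best) return(invisible())
    if (mg >= dose) {
      best <<- cost
      return(invisible())
    }
    if (i > n) return(invisible())
    for (k in 0:ceiling((dose - mg) / vials$size_mg[i]))
      rec(i + 1L, mg + k * vials$size_mg[i], cost + k * vials$price[i])
    invisible()
  }
  rec(1L, 0, 0)
  best
}

# Closed-form discounted person-time for an exponential state: integral of
# exp(-lambda * t) * exp(-rho * t) over [0, T] years.
exp_person_time <- function(lambda_yearly, rho, horizon_years) {
  (1 - exp(-(lambda_yearly + rho) * horizon_years)) / (lambda_yearly + rho)
}

# Quick arm_result for compare_arms identity checks.
make_arm_result <- function(cost, qalys, setting = "US", label = "arm") {
  structure(list(total_cost = cost, total_qalys = qalys,
                 total_life_years = qalys, label = label, setting = setting),
            class = "arm_result")
}
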