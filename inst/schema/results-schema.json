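{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "deatonuv pipeline results",
  "type": "object",
  "required": ["run", "summary", "anova", "within", "between", "elasticities", "robustness"],
  "properties": {
    "run": {
      "type": "object",
      "required": ["seed", "bootstrap_B", "pack_size", "exclusions"],
      "properties": {
        "seed": {"type": "integer"},
        "bootstrap_B": {"type": "integer"},
        "pack_size": {"type": "number"}
      }
    },
    "summary": {
      "type": "object",
      "required": ["n_households", "n_clusters", "households_per_cluster",
                   "mean_budget_share_pct", "mean_unit_value",
                   "mean_quantity_packs", "mean_total_expenditure"],
      "properties": {
        "n_households": {"type": "integer"},
        "n_clusters": {"type": "integer"},
        "households_per_cluster": {"type": "number"},
        "mean_budget_share_pct": {"type": "number"},
        "mean_unit_value": {"type": "number"},
        "mean_quantity_packs": {"type": "number"},
        "mean_total_expenditure": {"type": "number"}
      }
    },
    "anova": {
      "type": "object",
      "required": ["f_statistic", "p_value", "r_squared", "n_households", "n_clusters"],
      "properties": {
        "f_statistic": {"type": "number"},
        "p_value": {"type": "number"},
        "r_squared": {"type": "number"},
        "n_households": {"type": "integer"},
        "n_clusters": {"type": "integer"}
      }
    },
    "within": {
      "type": "object",
      "required": ["unit_value", "budget_share", "sigma11", "sigma12"],
      "properties": {
        "sigma11": {"type": "number"},
        "sigma12": {"type": "number"}
      }
    },
    "between": {
      "type": "object",
      "required": ["phi_hat", "phi_uncorrected", "cov_y2_y1", "var_y1",
                   "correction_num", "correction_den", "n_clusters_used"],
      "properties": {
        "phi_hat": {"type": "number"},
        "phi_uncorrected": {"type": "number"},
        "cov_y2_y1": {"type": "number"},
        "var_y1": {"type": "number"},
        "correction_num": {"type": "number"},
        "correction_den": {"type": "number"},
        "n_clusters_used": {"type": "integer"}
      }
    },
    "elasticities": {
      "type": "object",
      "required": ["w_bar", "beta_hat", "epsilon_hat", "phi_hat", "zeta_hat",
                   "theta_hat", "psi_hat", "price_elasticity",
                   "expenditure_elasticity", "n_households", "n_clusters"],
      "properties": {
        "w_bar": {"type": "number"},
        "beta_hat": {"type": "number"},
        "epsilon_hat": {"type": "number"},
        "phi_hat": {"type": "number"},
        "zeta_hat": {"type": "number"},
        "theta_hat": {"type": "number"},
        "psi_hat": {"type": "number"},
        "price_elasticity": {"type": "number"},
        "expenditure_elasticity": {"type": "number"},
        "n_households": {"type": "integer"},
        "n_clusters": {"type": "integer"}
      }
    },
    "robustness": {"type": "object"}
  }
}
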