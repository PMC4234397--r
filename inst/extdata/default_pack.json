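{
  "schema_version": "1.0",
  "units": "percent",
  "interventions": [
    {
      "name": "rotavirus_vaccine",
      "role": "prevention",
      "efficacy": 0,
      "incidence_efficacy": 50,
      "incidence_affected_fraction": 100,
      "age_band": [1, 59]
    },
    {
      "name": "vitamin_a",
      "role": "prevention",
      "efficacy": 0,
      "affected_fraction": 100,
      "age_band": [6, 59]
    },
    {
      "name": "preventive_zinc",
      "role": "prevention",
      "efficacy": 0,
      "affected_fraction": 100,
      "age_band": [12, 59]
    },
    {
      "name": "ors",
      "role": "treatment",
      "observed_effect": 69,
      "observed_coverage": 74,
      "affected_fraction": 100,
      "age_band": [1, 59]
    },
    {
      "name": "zinc_treatment",
      "role": "treatment",
      "efficacy": 23,
      "affected_fraction": 100,
      "age_band": [1, 59]
    },
    {
      "name": "antibiotics_dysentery",
      "role": "treatment",
      "efficacy": 99,
      "etiology": "dysentery",
      "age_band": [1, 59]
    }
  ],
  "breastfeeding": {
    "bands": {
      "0-1": {
        "baseline": {"exclusive": 62.0, "predominant": 25.0, "partial": 10.3, "none": 2.7},
        "promotion": {"mode": "target_rate", "value": 69.6}
      },
      "1-5": {
        "baseline": {"exclusive": 40.2, "predominant": 29.1, "partial": 29.2, "none": 1.5},
        "promotion": {"mode": "target_rate", "value": 54.5}
      }
    },
    "rrs": {
      "0-1": {"exclusive": 1, "predominant": 1, "partial": 1, "none": 1},
      "1-5": {"exclusive": 1, "predominant": 1, "partial": 1, "none": 1}
    },
    "death_shares": null
  },
  "etiology_fractions": {
    "region": "global",
    "fractions": {
      "dysentery": 3.9,
      "rotavirus": null
    }
  },
  "risk_factors": {
    "stunting": {
      "strata": ["z>=-1", "-1>z>=-2", "-2>z>=-3", "z<-3"],
      "prevalences": [40, 25, 20, 15],
      "mortality_rr": [1, 1, 1, 1],
      "affected": [false, false, true, true]
    }
  },
  "pathway_params": {
    "odds_per_episode": null,
    "episodes_per_child_year": null
  },
  "custom_interventions": [
    {"name": "vaccine_b", "links": null},
    {"name": "vaccine_c", "links": null}
  ]
}
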