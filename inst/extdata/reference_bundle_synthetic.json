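{
  "schema_version": "1.0",
  "model_type": "mrs6",
  "centering_mean": 73.69,
  "truncation_age": 100,
  "mortality": {
    "year1": {
      "family": "logistic-binary",
      "coefficients": {
        "intercept": -3.15332683895983,
        "age": 0.0664294976364687,
        "male": 0.266045569059869,
        "mrs1": 0.609013188903449,
        "mrs2": 0.440891691920895,
        "mrs3": 1.13706275893165,
        "mrs4": 2.32763766130367,
        "mrs5": 3.38900299005915
      }
    },
    "lifetime": {
      "family": "gompertz",
      "coefficients": {
        "intercept": -4.29925666195036,
        "age": 0.105458450916257,
        "age_sq": -0.00171633390753194,
        "male": 0.128962124679825,
        "mrs1": 0.154260455797238,
        "mrs2": 0.870567110165228,
        "mrs3": 1.64255126971484,
        "mrs4": 1.96787475198769,
        "mrs5": 3.90984316029672,
        "age_x_mrs1": 0.0329657233115196,
        "age_x_mrs2": 0.0248104143286104,
        "age_x_mrs3": 0.0177615640171141,
        "age_x_mrs4": -0.0340311797862814,
        "age_x_mrs5": -0.0815050318553788
      },
      "shape": {
        "gamma": 0.228699505147769
      }
    },
    "sim_meta": {
      "source": "calibrated to published grids"
    }
  },
  "resources": {
    "ed": {
      "family": "weibull",
      "coefficients": {
        "intercept": -0.279275478780049,
        "age": 0.00402602515482971,
        "male": -0.0653495355846866,
        "mrs1": 0.234554149708592,
        "mrs2": 0.469108299417185,
        "mrs3": 0.703662449125777,
        "mrs4": 0.635841593658463,
        "mrs5": 0.56802073819115
      },
      "shape": {
        "ln_p": -0.2019366986161
      }
    },
    "nonelective": {
      "family": "loglogistic",
      "coefficients": {
        "intercept": -1.02958009508523,
        "age": -0.0251383951798229,
        "male": 0.293505292477014,
        "mrs1": -0.451248534510409,
        "mrs2": -0.902497069020819,
        "mrs3": -1.35374560353123,
        "mrs4": -1.04260856827525,
        "mrs5": -0.731471533019275
      },
      "shape": {
        "ln_gamma": -1.83401301459791
      }
    },
    "elective": {
      "family": "loglogistic",
      "coefficients": {
        "intercept": 0.145185528011103,
        "age": -0.00919462376885312,
        "male": -0.0817830606897088,
        "mrs1": 0.32960612036832,
        "mrs2": 0.659212240736639,
        "mrs3": 0.988818361104959,
        "mrs4": 0.228915572682514,
        "mrs5": -0.53098721573993
      },
      "shape": {
        "ln_gamma": -0.18480254258163
      }
    }
  },
  "economics": {
    "unit_costs": {
      "ed_attendance": 137,
      "nonelective_bed_day": 533,
      "elective_bed_day": 444
    },
    "utilities": {
      "0": 0.97,
      "1": 0.88,
      "2": 0.74,
      "3": 0.55,
      "4": 0.2,
      "5": -0.19
    },
    "discount_rate": 0.035,
    "currency": "GBP"
  },
  "lifetime_count_method": "at_median",
  "metadata": {
    "source": "synthetic transcription stand-in: calibrated by least squares to the published survival and prediction grids",
    "calibration": {
      "mortality_sse": 1995.4399900896,
      "count_method": "at_median",
      "count_sse": [32.880113088932, 234.359971345788],
      "interpolated_states": "mrs0/mrs2/mrs4 resource levels interpolated"
    }
  }
}
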