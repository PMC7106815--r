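{
  "A": {
    "name": "Model A (CaV activation)",
    "intercept": -3.1819,
    "coefficients": {
      "k2alpha": -0.0413,
      "Id": -0.0003,
      "IdwAverage": 0.5530
    },
    "metadata": {
      "source": "published activation model",
      "response": "pIC50",
      "n_train": 20,
      "n_test": 4,
      "p": 3,
      "printed_stats": {
        "f_stat": { "value": 3.9664, "status": "printed_unreproduced" },
        "r2": { "value": 0.3182, "status": "printed_reproduced" },
        "q2": { "value": 0.0693, "status": "printed_unreproduced" },
        "r2_pred": { "value": 0.9586, "status": "printed_reproduced" },
        "r2_se": { "value": 0.0933, "status": "printed_reproduced" },
        "q2_se": { "value": 0.1090, "status": "printed_unreproduced" },
        "r2_pred_se": { "value": 0.0204, "status": "printed_unreproduced" }
      }
    }
  },
  "B": {
    "name": "Model B (CaV inhibition)",
    "intercept": 1.9116,
    "coefficients": {
      "Most+vePotential": 0.3241,
      "MomInertiaY": 0.0000,
      "DeltaEpsilonC": -0.3600
    },
    "metadata": {
      "source": "published inhibition model",
      "response": "pIC50",
      "n_train": 20,
      "n_test": 3,
      "p": 3,
      "printed_stats": {
        "f_stat": { "value": 1.5682, "status": "printed_unreproduced" },
        "r2": { "value": 0.0845, "status": "printed_unreproduced" },
        "q2": { "value": 0.1148, "status": "printed_unreproduced" },
        "r2_pred": { "value": 0.5227, "status": "printed_unreproduced" },
        "r2_se": { "value": 0.0804, "status": "printed_unreproduced" },
        "q2_se": { "value": 0.0887, "status": "printed_unreproduced" },
        "r2_pred_se": { "value": 0.0387, "status": "printed_unreproduced" }
      }
    }
  }
}
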