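{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "spikenet network configuration",
  "description": "Network description consumed by read_network_config(): YAML or JSON with these keys. Units: mV, ms, nS, pF, pA; rates in 1/ms.",
  "type": "object",
  "required": ["neurons"],
  "properties": {
    "schema_version": {"const": 1},
    "neurons": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "properties": {
          "g_leak": {"type": "number", "exclusiveMinimum": 0},
          "C_m": {"type": "number", "exclusiveMinimum": 0},
          "E_rest": {"type": "number"},
          "E_exc": {"type": "number"},
          "E_inh": {"type": "number"},
          "r0": {"type": "number", "exclusiveMinimum": 0},
          "V_T": {"type": "number"},
          "dV": {"type": "number", "exclusiveMinimum": 0},
          "r_max": {"type": "number", "exclusiveMinimum": 0},
          "refractory_abs": {"type": "number", "minimum": 0},
          "bias_current": {"type": "number"},
          "is_inhibitory": {"type": "boolean"}
        },
        "additionalProperties": false
      }
    },
    "synapses": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pre", "post", "weight"],
        "properties": {
          "pre": {"type": "integer", "minimum": 1},
          "post": {"type": "integer", "minimum": 1},
          "weight": {"type": "number", "minimum": 0},
          "delay": {"type": "number", "exclusiveMinimum": 0},
          "kind": {"enum": ["conductance-exp", "current-rect"]},
          "pulse_length": {"type": "number", "exclusiveMinimum": 0},
          "U": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
          "D": {"type": "number", "exclusiveMinimum": 0},
          "F": {"type": "number", "exclusiveMinimum": 0}
        },
        "additionalProperties": false
      }
    },
    "inputs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["neuron_ids", "kind"],
        "properties": {
          "neuron_ids": {"type": "array", "items": {"type": "integer"}},
          "kind": {"enum": ["constant", "markov-modulated"]},
          "rate": {"type": ["number", "array"]},
          "modulator": {
            "type": "object",
            "required": ["rates", "Q_dwell"],
            "properties": {
              "rates": {"type": "array", "items": {"type": "number"}},
              "Q_dwell": {"type": "array", "items": {"type": "number"}},
              "P": {"type": "array"}
            }
          }
        },
        "additionalProperties": false
      }
    },
    "threshold_modulation": {
      "type": "object",
      "required": ["amplitude", "period"],
      "properties": {
        "amplitude": {"type": "number"},
        "period": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "tau_syn_exc": {"type": "number", "exclusiveMinimum": 0},
    "tau_syn_inh": {"type": "number", "exclusiveMinimum": 0}
  }
}
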