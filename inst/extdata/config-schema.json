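{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mdximmune run configuration",
  "type": "object",
  "required": ["experiment", "out_dir"],
  "properties": {
    "experiment": {
      "enum": ["simulate", "wildtype", "deplete", "fit", "recover",
               "sweep", "heatmap", "ensemble", "synth"]
    },
    "out_dir": {"type": "string", "description": "output directory"},
    "params": {"type": "string",
               "description": "path to flat parameter JSON (keys k1..k6, dH, dC, dM, dD, h, m, sigma, H0, C0, M0)"},
    "seed": {"type": "integer", "default": 1},
    "horizon": {"type": "number", "description": "weeks", "default": 12},
    "step": {"type": "number", "description": "output step, weeks", "default": 0.05},
    "target": {"enum": ["macrophages", "CD4", "CD8"]},
    "start": {"type": "number", "description": "depletion window start, weeks"},
    "end": {"type": "number", "description": "depletion window end, weeks"},
    "mechanism": {"enum": ["clamp_zero", "block_influx"]},
    "observations": {"type": "string",
                     "description": "CSV with dataset_id,variable,time_days,value,weight"},
    "budget": {"type": "integer", "description": "global-stage objective evaluations"},
    "cv": {"type": "number", "description": "count-noise coefficient of variation"},
    "replicates": {"type": "integer"},
    "param": {"type": "string", "description": "swept parameter name"},
    "from": {"type": "number"},
    "to": {"type": "number"},
    "by": {"type": "number"},
    "week": {"type": "number", "description": "heat-map snapshot week"},
    "variable": {"enum": ["H", "C", "M", "N", "D", "R"]},
    "n": {"type": "integer", "description": "ensemble size"}
  }
}
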