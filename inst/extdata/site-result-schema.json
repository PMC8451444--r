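{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "apiary site evaluation result",
  "type": "object",
  "propertyOrder": ["x", "y", "onRoad", "honey", "hives"],
  "required": ["x", "y", "onRoad", "honey", "hives"],
  "additionalProperties": false,
  "properties": {
    "x": {"type": "number", "description": "site x coordinate, input units"},
    "y": {"type": "number", "description": "site y coordinate, input units"},
    "onRoad": {"type": "boolean", "description": "site lies on a road polyline"},
    "honey": {"type": "number", "minimum": 0, "description": "total collectible honey, kg"},
    "hives": {"type": "integer", "minimum": 0, "description": "supportable colony count"}
  }
}
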