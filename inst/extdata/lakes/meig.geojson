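{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"lake","name":"Meig","approximate":true,"area_km2":0.4499998946},"geometry":{"type":"Polygon","coordinates":[[[753.9,0],[759.65,7.46],[763.55,15.02],[765.21,22.64],[764.32,30.26],[760.66,37.83],[754.1,45.26],[744.64,52.5],[732.38,59.49],[717.54,66.18],[700.42,72.53],[681.38,78.53],[660.85,84.18],[639.27,89.5],[617.06,94.53],[594.62,99.33],[572.31,103.95],[550.39,108.47],[529.04,112.96],[508.36,117.48],[488.35,122.09],[468.92,126.82],[449.92,131.7],[431.12,136.72],[412.28,141.87],[393.14,147.09],[373.41,152.34],[352.88,157.53],[331.35,162.58],[308.68,167.4],[284.8,171.89],[259.71,175.99],[233.45,179.62],[206.15,182.74],[177.95,185.3],[149.03,187.31],[119.6,188.78],[89.83,189.73],[59.89,190.23],[29.91,190.34],[0,190.13],[-29.81,189.68],[-59.52,189.05],[-89.16,188.32],[-118.81,187.53],[-148.56,186.71],[-178.5,185.88],[-208.71,185.01],[-239.24,184.08],[-270.09,183.03],[-301.23,181.81],[-332.52,180.32],[-363.81,178.51],[-394.86,176.27],[-425.39,173.54],[-455.08,170.27],[-483.6,166.4],[-510.61,161.93],[-535.8,156.83],[-558.91,151.16],[-579.74,144.93],[-598.17,138.23],[-614.17,131.14],[-627.81,123.73],[-639.26,116.11],[-648.75,108.37],[-656.61,100.59],[-663.21,92.85],[-668.95,85.21],[-674.24,77.71],[-679.44,70.36],[-684.88,63.17],[-690.83,56.12],[-697.44,49.17],[-704.76,42.3],[-712.75,35.44],[-721.25,28.56],[-729.98,21.6],[-738.62,14.53],[-746.74,7.33],[-753.9,0],[-759.65,-7.46],[-763.55,-15.02],[-765.21,-22.64],[-764.32,-30.26],[-760.66,-37.83],[-754.1,-45.26],[-744.64,-52.5],[-732.38,-59.49],[-717.54,-66.18],[-700.42,-72.53],[-681.38,-78.53],[-660.85,-84.18],[-639.27,-89.5],[-617.06,-94.53],[-594.62,-99.33],[-572.31,-103.95],[-550.39,-108.47],[-529.04,-112.96],[-508.36,-117.48],[-488.35,-122.09],[-468.92,-126.82],[-449.92,-131.7],[-431.12,-136.72],[-412.28,-141.87],[-393.14,-147.09],[-373.41,-152.34],[-352.88,-157.53],[-331.35,-162.58],[-308.68,-167.4],[-284.8,-171.89],[-259.71,-175.99],[-233.45,-179.62],[-206.15,-182.74],[-177.95,-185.3],[-149.03,-187.31],[-119.6,-188.78],[-89.83,-189.73],[-59.89,-190.23],[-29.91,-190.34],[-0,-190.13],[29.81,-189.68],[59.52,-189.05],[89.16,-188.32],[118.81,-187.53],[148.56,-186.71],[178.5,-185.88],[208.71,-185.01],[239.24,-184.08],[270.09,-183.03],[301.23,-181.81],[332.52,-180.32],[363.81,-178.51],[394.86,-176.27],[425.39,-173.54],[455.08,-170.27],[483.6,-166.4],[510.61,-161.93],[535.8,-156.83],[558.91,-151.16],[579.74,-144.93],[598.17,-138.23],[614.17,-131.14],[627.81,-123.73],[639.26,-116.11],[648.75,-108.37],[656.61,-100.59],[663.21,-92.85],[668.95,-85.21],[674.24,-77.71],[679.44,-70.36],[684.88,-63.17],[690.83,-56.12],[697.44,-49.17],[704.76,-42.3],[712.75,-35.44],[721.25,-28.56],[729.98,-21.6],[738.62,-14.53],[746.74,-7.33],[753.9,0]]]}},{"type":"Feature","properties":{"role":"start","initial_bearing":90},"geometry":{"type":"Point","coordinates":[-753.9,0]}},{"type":"Feature","properties":{"role":"capture_center","radius":9.59892475628915,"exposed_perimeter":29},"geometry":{"type":"Point","coordinates":[753.9,0]}}]}
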