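{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"lake","name":"Garve","approximate":true,"area_km2":1.8300000224},"geometry":{"type":"Polygon","coordinates":[[[1108.45,0],[1113.5,23.03],[1115.9,46.22],[1115.58,69.49],[1112.49,92.74],[1106.61,115.85],[1097.95,138.73],[1086.57,161.29],[1072.54,183.42],[1055.96,205.03],[1036.95,226.06],[1015.67,246.44],[992.28,266.1],[966.93,285],[939.83,303.12],[911.13,320.42],[881.04,336.9],[849.71,352.56],[817.31,367.4],[784.01,381.44],[749.93,394.7],[715.2,407.21],[679.93,419],[644.21,430.09],[608.11,440.52],[571.7,450.32],[535.01,459.5],[498.07,468.09],[460.91,476.1],[423.55,483.55],[385.97,490.43],[348.2,496.75],[310.22,502.51],[272.04,507.68],[233.67,512.27],[195.11,516.24],[156.36,519.6],[117.46,522.31],[78.41,524.36],[39.25,525.73],[0,526.41],[-39.29,526.38],[-78.6,525.63],[-117.87,524.17],[-157.08,521.98],[-196.17,519.06],[-235.11,515.43],[-273.87,511.09],[-312.4,506.03],[-350.68,500.29],[-388.67,493.86],[-426.35,486.75],[-463.69,478.97],[-500.68,470.54],[-537.28,461.45],[-573.46,451.71],[-609.2,441.31],[-644.45,430.25],[-679.17,418.53],[-713.31,406.13],[-746.8,393.05],[-779.56,379.27],[-811.51,364.79],[-842.55,349.59],[-872.56,333.66],[-901.42,317.01],[-929,299.63],[-955.16,281.53],[-979.74,262.74],[-1002.61,243.27],[-1023.61,223.15],[-1042.6,202.44],[-1059.44,181.18],[-1074.02,159.42],[-1086.21,137.25],[-1095.94,114.73],[-1103.12,91.96],[-1107.72,69],[-1109.72,45.97],[-1109.13,22.94],[-1105.97,0],[-1100.32,-22.75],[-1092.25,-45.24],[-1081.89,-67.4],[-1069.37,-89.14],[-1054.84,-110.43],[-1038.47,-131.22],[-1020.43,-151.47],[-1000.91,-171.17],[-980.1,-190.3],[-958.16,-208.89],[-935.27,-226.93],[-911.59,-244.46],[-887.26,-261.52],[-862.4,-278.15],[-837.09,-294.38],[-811.42,-310.28],[-785.42,-325.88],[-759.11,-341.23],[-732.49,-356.37],[-705.53,-371.33],[-678.16,-386.12],[-650.33,-400.76],[-621.94,-415.23],[-592.92,-429.52],[-563.15,-443.59],[-532.56,-457.4],[-501.03,-470.87],[-468.51,-483.95],[-434.92,-496.53],[-400.22,-508.53],[-364.39,-519.85],[-327.42,-530.37],[-289.36,-539.99],[-250.25,-548.62],[-210.18,-556.14],[-169.26,-562.47],[-127.62,-567.52],[-85.42,-571.24],[-42.82,-573.56],[-0,-574.45],[42.84,-573.9],[85.52,-571.9],[127.84,-568.48],[169.63,-563.67],[210.71,-557.53],[250.94,-550.13],[290.19,-541.55],[328.36,-531.89],[365.37,-521.25],[401.16,-509.73],[435.72,-497.45],[469.07,-484.52],[501.22,-471.05],[532.24,-457.13],[562.21,-442.85],[591.23,-428.29],[619.39,-413.52],[646.82,-398.59],[673.62,-383.54],[699.91,-368.38],[725.79,-353.11],[751.34,-337.74],[776.63,-322.23],[801.7,-306.56],[826.58,-290.68],[851.24,-274.55],[875.65,-258.1],[899.75,-241.29],[923.43,-224.06],[946.57,-206.36],[969.01,-188.15],[990.59,-169.4],[1011.12,-150.09],[1030.4,-130.2],[1048.22,-109.74],[1064.37,-88.73],[1078.66,-67.19],[1090.88,-45.19],[1100.87,-22.76],[1108.45,0]]]}},{"type":"Feature","properties":{"role":"start","initial_bearing":89.9999935242619},"geometry":{"type":"Point","coordinates":[-1105.97,0]}},{"type":"Feature","properties":{"role":"capture_center","radius":16.4692095130823,"exposed_perimeter":50},"geometry":{"type":"Point","coordinates":[1108.45,0]}}]}
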