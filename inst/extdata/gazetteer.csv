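name,country,lat,lon,kind
Los Angeles,USA,34.0522,-118.2437,place
San Francisco,USA,37.7749,-122.4194,place
Seattle,USA,47.6062,-122.3321,place
Boulder,USA,40.0150,-105.2705,place
Miami,USA,25.7617,-80.1918,place
Boston,USA,42.3601,-71.0589,place
Vancouver,Canada,49.2827,-123.1207,place
Toronto,Canada,43.6532,-79.3832,place
Mexico City,Mexico,19.4326,-99.1332,place
Manaus,Brazil,-3.1190,-60.0217,place
Sao Paulo,Brazil,-23.5505,-46.6333,place
Buenos Aires,Argentina,-34.6037,-58.3816,place
Santiago,Chile,-33.4489,-70.6693,place
Lima,Peru,-12.0464,-77.0428,place
Reykjavik,Iceland,64.1466,-21.9426,place
Dublin,Ireland,53.3498,-6.2603,place
Lisbon,Portugal,38.7223,-9.1393,place
Madrid,Spain,40.4168,-3.7038,place
Paris,France,48.8566,2.3522,place
Zurich,Switzerland,47.3769,8.5417,place
Oslo,Norway,59.9139,10.7522,place
Berlin,Germany,52.5200,13.4050,place
Rome,Italy,41.9028,12.4964,place
Stockholm,Sweden,59.3293,18.0686,place
Athens,Greece,37.9838,23.7275,place
Helsinki,Finland,60.1699,24.9384,place
Cairo,Egypt,30.0444,31.2357,place
Moscow,Russia,55.7558,37.6173,place
Nairobi,Kenya,-1.2921,36.8219,place
Cape Town,South Africa,-33.9249,18.4241,place
Dubai,United Arab Emirates,25.2048,55.2708,place
Mumbai,India,19.0760,72.8777,place
New Delhi,India,28.6139,77.2090,place
Kathmandu,Nepal,27.7172,85.3240,place
Bangkok,Thailand,13.7563,100.5018,place
Singapore,Singapore,1.3521,103.8198,place
Hanoi,Vietnam,21.0278,105.8342,place
Perth,Australia,-31.9505,115.8605,place
Beijing,China,39.9042,116.4074,place
Shanghai,China,31.2304,121.4737,place
Manila,Philippines,14.5995,120.9842,place
Seoul,South Korea,37.5665,126.9780,place
Tokyo,Japan,35.6762,139.6503,place
Sapporo,Japan,43.0618,141.3545,place
Sydney,Australia,-33.8688,151.2093,place
Brisbane,Australia,-27.4698,153.0251,place
Auckland,New Zealand,-36.8485,174.7633,place
Anchorage,USA,61.2181,-149.9003,place
Honolulu,USA,21.3099,-157.8581,place
McMurdo Station,Antarctica,-77.8419,166.6863,place
University of Zurich,Switzerland,47.3975,8.5481,institution
Scripps Institution of Oceanography,USA,32.8669,-117.2533,institution
Wageningen University,Netherlands,51.9856,5.6630,institution
University of Queensland,Australia,-27.4975,153.0137,institution
Max Planck Institute Bremen,Germany,53.1096,8.8017,institution
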