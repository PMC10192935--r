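# Bundled list of real U.S. city/state pairs used by the synthetic generator.
# Real place names make edit-distance similarities (and typo perturbations)
# behave like they do on real exports.

#' U.S. city/state pairs used by the synthetic universe
#'
#' @return A tibble with columns `city` and `state` (USPS code).
#' @export
us_cities <- function() {
  raw <- c(
    "Birmingham:AL", "Montgomery:AL", "Mobile:AL", "Huntsville:AL",
    "Anchorage:AK", "Phoenix:AZ", "Tucson:AZ", "Mesa:AZ", "Chandler:AZ",
    "Glendale:AZ", "Little Rock:AR", "Fort Smith:AR", "Los Angeles:CA",
    "San Diego:CA", "San Jose:CA", "San Francisco:CA", "Fresno:CA",
    "Sacramento:CA", "Long Beach:CA", "Oakland:CA", "Bakersfield:CA",
    "Stockton:CA", "Riverside:CA", "Santa Ana:CA", "Modesto:CA",
    "San Bernardino:CA", "Denver:CO", "Colorado Springs:CO", "Aurora:CO",
    "Pueblo:CO", "Bridgeport:CT", "New Haven:CT", "Hartford:CT",
    "Wilmington:DE", "Dover:DE", "Washington:DC", "Jacksonville:FL",
    "Miami:FL", "Tampa:FL", "Orlando:FL", "St. Petersburg:FL",
    "Hialeah:FL", "Tallahassee:FL", "Fort Lauderdale:FL", "Pensacola:FL",
    "Atlanta:GA", "Columbus:GA", "Augusta:GA", "Savannah:GA", "Macon:GA",
    "Honolulu:HI", "Boise:ID", "Chicago:IL", "Aurora:IL", "Rockford:IL",
    "Joliet:IL", "Naperville:IL", "Springfield:IL", "Peoria:IL",
    "Indianapolis:IN", "Fort Wayne:IN", "Evansville:IN", "South Bend:IN",
    "Gary:IN", "Des Moines:IA", "Cedar Rapids:IA", "Davenport:IA",
    "Wichita:KS", "Overland Park:KS", "Kansas City:KS", "Topeka:KS",
    "Louisville:KY", "Lexington:KY", "Bowling Green:KY", "New Orleans:LA",
    "Baton Rouge:LA", "Shreveport:LA", "Lafayette:LA", "Portland:ME",
    "Baltimore:MD", "Frederick:MD", "Rockville:MD", "Boston:MA",
    "Worcester:MA", "Springfield:MA", "Lowell:MA", "Detroit:MI",
    "Grand Rapids:MI", "Warren:MI", "Flint:MI", "Lansing:MI",
    "Minneapolis:MN", "St. Paul:MN", "Rochester:MN", "Duluth:MN",
    "Jackson:MS", "Gulfport:MS", "Biloxi:MS", "Kansas City:MO",
    "St. Louis:MO", "Springfield:MO", "Columbia:MO", "Billings:MT",
    "Missoula:MT", "Omaha:NE", "Lincoln:NE", "Las Vegas:NV", "Reno:NV",
    "Henderson:NV", "Manchester:NH", "Nashua:NH", "Newark:NJ",
    "Jersey City:NJ", "Paterson:NJ", "Trenton:NJ", "Camden:NJ",
    "Albuquerque:NM", "Las Cruces:NM", "Santa Fe:NM", "New York:NY",
    "Buffalo:NY", "Rochester:NY", "Yonkers:NY", "Syracuse:NY",
    "Albany:NY", "Charlotte:NC", "Raleigh:NC", "Greensboro:NC",
    "Durham:NC", "Winston-Salem:NC", "Fayetteville:NC", "Wilmington:NC",
    "Fargo:ND", "Bismarck:ND", "Columbus:OH", "Cleveland:OH",
    "Cincinnati:OH", "Toledo:OH", "Akron:OH", "Dayton:OH", "Youngstown:OH",
    "Oklahoma City:OK", "Tulsa:OK", "Norman:OK", "Portland:OR",
    "Salem:OR", "Eugene:OR", "Philadelphia:PA", "Pittsburgh:PA",
    "Allentown:PA", "Erie:PA", "Reading:PA", "Scranton:PA",
    "Providence:RI", "Warwick:RI", "Columbia:SC", "Charleston:SC",
    "North Charleston:SC", "Greenville:SC", "Sioux Falls:SD",
    "Rapid City:SD", "Memphis:TN", "Nashville:TN", "Knoxville:TN",
    "Chattanooga:TN", "Clarksville:TN", "Houston:TX", "San Antonio:TX",
    "Dallas:TX", "Austin:TX", "Fort Worth:TX", "El Paso:TX",
    "Arlington:TX", "Corpus Christi:TX", "Plano:TX", "Laredo:TX",
    "Lubbock:TX", "Garland:TX", "Amarillo:TX", "Brownsville:TX",
    "Waco:TX", "Odessa:TX", "Salt Lake City:UT", "Provo:UT",
    "West Valley City:UT", "Burlington:VT", "Virginia Beach:VA",
    "Norfolk:VA", "Chesapeake:VA", "Richmond:VA", "Newport News:VA",
    "Roanoke:VA", "Seattle:WA", "Spokane:WA", "Tacoma:WA", "Vancouver:WA",
    "Everett:WA", "Charleston:WV", "Huntington:WV", "Milwaukee:WI",
    "Madison:WI", "Green Bay:WI", "Kenosha:WI", "Racine:WI",
    "Cheyenne:WY", "Casper:WY"
  )
  parts <- stringr::str_split_fixed(raw, ":", 2)
  tibble::tibble(city = parts[, 1], state = parts[, 2])
}

# Name pools for synthetic shooters; sized so that full-name collisions
# between unrelated incidents are rare.
synthetic_first_names <- function() {
  c(
    "James", "Robert", "John", "Michael", "David", "William", "Richard",
    "Joseph", "Thomas", "Charles", "Christopher", "Daniel", "Matthew",
    "Anthony", "Mark", "Donald", "Steven", "Paul", "Andrew", "Joshua",
    "Kenneth", "Kevin", "Brian", "George", "Timothy", "Ronald", "Edward",
    "Jason", "Jeffrey", "Ryan", "Jacob", "Gary", "Nicholas", "Eric",
    "Jonathan", "Stephen", "Larry", "Justin", "Scott", "Brandon",
    "Benjamin", "Samuel", "Gregory", "Alexander", "Frank", "Patrick",
    "Raymond", "Jack", "Dennis", "Jerry", "Tyler", "Aaron", "Jose",
    "Adam", "Nathan", "Henry", "Zachary", "Douglas", "Peter", "Kyle"
  )
}

synthetic_last_names <- function() {
  c(
    "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
    "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
    "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
    "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
    "Ramirez", "Lewis", "Robinson", "Walker", "Young", "Allen", "King",
    "Wright", "Scott", "Torres", "Nguyen", "Hill", "Flores", "Green",
    "Adams", "Nelson", "Baker", "Hall", "Rivera", "Campbell", "Mitchell",
    "Carter", "Roberts", "Gomez", "Phillips", "Evans", "Turner", "Diaz",
    "Parker", "Cruz", "Edwards", "Collins", "Reyes", "Stewart", "Morris",
    "Morales", "Murphy", "Cook", "Rogers", "Gutierrez", "Ortiz", "Morgan",
    "Cooper", "Peterson", "Bailey", "Reed", "Kelly", "Howard", "Ramos",
    "Kim", "Cox", "Ward", "Richardson"
  )
}
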